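## Onboarding: PCR primer tails that convert an arbitrary template into a
## Mobius Level 0 standard part via the universal acceptor.

SPACER_CHOICES <- c("AAAA", "CAAA", "TACA", "CTAA", "ATCA", "TTCA")

## Wallace rule melting estimate: 2(A+T) + 4(G+C). A design aid only.
wallace_tm <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

pick_anneal <- function(seq, len_range, tm_range) {
  lens <- len_range[1]:min(len_range[2], nchar(seq))
  if (!length(lens) || max(lens) < len_range[1])
    stop("template too short for an annealing region", call. = FALSE)
  cands <- vapply(lens, function(l) wallace_tm(substr(seq, 1, l)), numeric(1))
  ok <- which(cands >= tm_range[1] & cands <= tm_range[2])
  if (!length(ok))
    stop(sprintf(
      "annealing Tm out of bounds: achievable %d-%d C, wanted %d-%d C",
      min(cands), max(cands), tm_range[1], tm_range[2]), call. = FALSE)
  l <- lens[ok[1]]
  list(seq = substr(seq, 1, l), tm = cands[ok[1]])
}

## A tail must contain exactly its one intended AarI site and no BsaI
## site, also against the first bases of the cargo it abuts.
tail_is_clean <- function(tail, cargo_head) {
  probe <- dna_molecule("tail", paste0(tail, cargo_head), "linear")
  nrow(find_sites(probe, "AarI")) == 1L && nrow(find_sites(probe, "BsaI")) == 0L
}

#' Design onboarding primers for a new standard part
#'
#' Builds the forward/reverse primer pair that turns a template sequence
#' into a Mobius Level 0 part: each primer is, 5' to 3', a short GC clamp,
#' the AarI recognition CACCTGC, a 4-nt spacer matching AarI's (4/8)
#' geometry so the cut lands exactly on the fusion 4-mer, the mUAV fusion
#' site (CTCT forward, reverse complement of TGAG reverse), the standard
#' part overhang for the chosen role, and an annealing region sized to a
#' Wallace-rule melting window.  Spacer bases default to AAAA and are
#' switched from a fixed alphabet if they would create an unintended site.
#'
#' The template must be free of internal AarI/BsaI sites; otherwise a
#' domestication-required error points at [domesticate_cds()].
#'
#' @param template A `dna_molecule` holding the cargo to onboard (linear).
#' @param role Standard part role (`"promoter"`, `"CDS"`, `"terminator"`,
#'   `"custom"`), or supply `overhangs` directly.
#' @param overhangs Optional explicit `c(left, right)` 4-mers.
#' @param clamp 5' clamp (default `"GG"`, 2-6 nt).
#' @param tm_range Annealing melting window in degrees C.
#' @param anneal_len_range Annealing length bounds.
#' @return A `primer_design`: `forward`/`reverse` (each with `sequence`,
#'   `tm`, `anneal`), `role`, `overhangs`, `template_id`.
#' @export
design_primers <- function(template, role = "CDS", overhangs = NULL,
                           clamp = "GG", tm_range = c(48, 68),
                           anneal_len_range = c(18, 25)) {
  stopifnot(is(template, "dna_molecule"))
  if (nchar(clamp) < 2 || nchar(clamp) > 6)
    stop("clamp must be 2-6 nt", call. = FALSE)
  rep_int <- scan_sites(template)
  if (rep_int$needs_domestication)
    stop("template '", template$id, "' contains internal AarI/BsaI site(s); ",
         "domestication required first (see domesticate_cds())", call. = FALSE)
  if (is.null(overhangs)) {
    spec <- part_type_spec(role)
    overhangs <- c(spec$left, spec$right)
  }
  seq <- template$sequence
  f_anneal <- pick_anneal(seq, anneal_len_range, tm_range)
  r_anneal <- pick_anneal(rc(seq), anneal_len_range, tm_range)

  make_tail <- function(fusion, overhang, cargo_head) {
    for (sp in SPACER_CHOICES) {
      tail <- paste0(clamp, "CACCTGC", sp, fusion, overhang)
      if (tail_is_clean(tail, cargo_head)) return(tail)
    }
    stop("could not build a clean primer tail for overhang ", overhang,
         call. = FALSE)
  }
  f_tail <- make_tail("CTCT", overhangs[1], substr(seq, 1, 10))
  r_tail <- make_tail(rc("TGAG"), rc(overhangs[2]),
                      substr(rc(seq), 1, 10))
  structure(list(
    forward = list(sequence = paste0(f_tail, f_anneal$seq),
                   tail = f_tail, anneal = f_anneal$seq, tm = f_anneal$tm),
    reverse = list(sequence = paste0(r_tail, r_anneal$seq),
                   tail = r_tail, anneal = r_anneal$seq, tm = r_anneal$tm),
    role = role, overhangs = overhangs, template_id = template$id),
    class = "primer_design")
}

#' @export
print.primer_design <- function(x, ...) {
  cat(sprintf("<primer_design> %s (%s, %s/%s)\n  F: %s (Tm %d)\n  R: %s (Tm %d)\n",
              x$template_id, x$role, x$overhangs[1], x$overhangs[2],
              x$forward$sequence, x$forward$tm,
              x$reverse$sequence, x$reverse$tm))
  invisible(x)
}

#' In-silico PCR amplicon for a primer design
#'
#' Concatenates the forward tail, the full template and the reverse
#' complement of the reverse tail (after verifying that both annealing
#' regions match the template ends).  Template features are carried over.
#'
#' @param design A `primer_design`.
#' @param template The template `dna_molecule` the design was made for.
#' @return Linear `dna_molecule` amplicon.
#' @export
pcr_amplicon <- function(design, template) {
  stopifnot(is(design, "primer_design"))
  seq <- template$sequence
  if (!startsWith(seq, design$forward$anneal) ||
      !startsWith(rc(seq), design$reverse$anneal))
    stop("primer annealing regions do not match template '", template$id, "'",
         call. = FALSE)
  amp <- paste0(design$forward$tail, seq, rc(design$reverse$tail))
  feats <- template$features
  if (nrow(feats)) {
    feats$start <- feats$start + nchar(design$forward$tail)
    feats$end <- feats$end + nchar(design$forward$tail)
  }
  dna_molecule(paste0(template$id, "::amplicon"), amp, "linear", feats)
}

#' Onboard a part into the universal acceptor
#'
#' Runs the full Level 0 route in silico: design primers (unless given),
#' amplify, and simulate the one-pot AarI reaction with the toolkit's
#' mUAV.  The resulting Level 0 plasmid stores the part behind
#' reconstituted BsaI sites.
#'
#' @param template Cargo `dna_molecule`.
#' @param toolkit A `mobius_toolkit`.
#' @param role,overhangs Passed to [design_primers()].
#' @param design Optional pre-made `primer_design`.
#' @return The Level 0 `assembly_product`.
#' @export
build_level0 <- function(template, toolkit, role = "CDS", overhangs = NULL,
                         design = NULL) {
  if (is.null(design))
    design <- design_primers(template, role = role, overhangs = overhangs)
  amp <- pcr_amplicon(design, template)
  res <- simulate_one_pot(reaction_mix(toolkit$vectors$mUAV, list(amp), "AarI"))
  if (res$diagnostics$failure_mode != "none")
    stop("mUAV reaction failed: ", res$diagnostics$failure_mode, " -- ",
         res$diagnostics$detail, call. = FALSE)
  res$product$molecule$id <- paste0("L0-", template$id)
  res$product
}

#' Verify a Level 0 storage plasmid
#'
#' Confirms the standard-part contract: exactly two BsaI sites, both
#' facing the cargo (cutting into it, recognitions on the backbone side);
#' zero AarI/BsaI sites inside the released cargo; and, when a role is
#' declared, release overhangs conforming to that role.
#'
#' @param level0 Circular `dna_molecule` (or `assembly_product`).
#' @param role Optional declared part role to check overhangs against.
#' @return List with `pass` flag, `checks` (named logicals), `overhangs`
#'   and `detail` lines for any failure.
#' @export
verify_part <- function(level0, role = NULL) {
  m <- if (is(level0, "assembly_product")) level0$molecule else level0
  checks <- c(two_bsai_sites = FALSE, sites_face_cargo = FALSE,
              cargo_site_free = FALSE, overhangs_conform = TRUE)
  detail <- character()
  overhangs <- c(NA_character_, NA_character_)

  hits <- find_sites(m, "BsaI")
  checks["two_bsai_sites"] <- nrow(hits) == 2L
  if (!checks["two_bsai_sites"]) {
    detail <- c(detail, sprintf("found %d BsaI site(s) at position(s) %s, expected 2",
                                nrow(hits), paste(hits$position, collapse = ", ")))
  } else {
    checks["sites_face_cargo"] <- setequal(hits$strand, c("+", "-"))
    if (!checks["sites_face_cargo"])
      detail <- c(detail, "the two BsaI sites do not face each other")
  }
  if (checks["two_bsai_sites"] && checks["sites_face_cargo"]) {
    frags <- digest(m, "BsaI")
    cargo_idx <- which(!vapply(frags, function(f)
      any(f$features$type == "resistance"), logical(1)))
    if (length(cargo_idx) == 1L) {
      cargo <- frags[[cargo_idx]]
      overhangs <- c(cargo$left_overhang, cargo$right_overhang)
      interior <- substr(cargo$core, 5L, nchar(cargo$core) - 4L)
      rep <- scan_sites(dna_molecule("cargo", interior, "linear"))
      checks["cargo_site_free"] <- !rep$needs_domestication
      if (!checks["cargo_site_free"])
        detail <- c(detail, sprintf("%d forbidden site(s) inside cargo",
                                    nrow(rep$hits)))
      if (!is.null(role)) {
        spec <- part_type_spec(role)
        checks["overhangs_conform"] <-
          identical(overhangs, c(spec$left, spec$right))
        if (!checks["overhangs_conform"])
          detail <- c(detail, sprintf("overhangs %s/%s do not match role %s (%s/%s)",
                                      overhangs[1], overhangs[2], role,
                                      spec$left, spec$right))
      }
    } else {
      detail <- c(detail, "could not isolate a unique cargo fragment")
    }
  }
  list(pass = all(checks), checks = as.list(checks),
       overhangs = overhangs, detail = detail)
}

#' Write primers as TSV and FASTA
#' @param designs A `primer_design` or list of them.
#' @param tsv,fasta Output paths (either may be `NULL` to skip).
#' @return Invisibly, the TSV rows.
#' @export
write_primers <- function(designs, tsv = NULL, fasta = NULL) {
  if (is(designs, "primer_design")) designs <- list(designs)
  rows <- do.call(rbind, lapply(designs, function(d) {
    data.frame(name = paste0(d$template_id, c("_F", "_R")),
               sequence = c(d$forward$sequence, d$reverse$sequence),
               tm = c(d$forward$tm, d$reverse$tm),
               role = d$role, stringsAsFactors = FALSE)
  }))
  if (!is.null(tsv))
    utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    mols <- lapply(seq_len(nrow(rows)), function(i)
      dna_molecule(rows$name[i], rows$sequence[i], "linear"))
    write_fasta(mols, fasta)
  }
  invisible(rows)
}
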