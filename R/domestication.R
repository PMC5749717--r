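#' Scan a molecule for forbidden Type IIS sites
#'
#' Finds every recognition site of each forbidden enzyme on both strands
#' and merges the hits into one report.
#'
#' @param m A `dna_molecule`.
#' @param forbidden List of enzymes (objects or names); defaults to the
#'   two Mobius assembly enzymes AarI and BsaI.
#' @return List of class `site_report`: `molecule` (id), `hits` (the
#'   merged [find_sites()] data frame) and `needs_domestication` flag.
#' @export
scan_sites <- function(m, forbidden = mobius_enzymes()) {
  hits <- do.call(rbind, lapply(forbidden, function(e) find_sites(m, e)))
  hits <- hits[order(hits$position, hits$enzyme), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(molecule = m$id, hits = hits,
                 needs_domestication = nrow(hits) > 0L),
            class = "site_report")
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("<site_report> %s: %d forbidden site(s)%s\n", x$molecule,
              nrow(x$hits),
              if (x$needs_domestication) " -- domestication needed" else ""))
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' Write a site report as TSV
#' @param report A `site_report` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(report, path) {
  if (is(report, "site_report")) report <- list(report)
  rows <- do.call(rbind, lapply(report, function(r) {
    if (!nrow(r$hits))
      return(NULL)
    data.frame(molecule = r$molecule, r$hits, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(molecule = character(), enzyme = character(),
                       position = integer(), strand = character(),
                       cut_top = integer(), cut_bottom = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected recognition-site density of an enzyme set
#'
#' Under an i.i.d. uniform-base model (GC = 50%), a non-palindromic
#' recognition sequence of length `L` occurs at an expected per-bp density
#' of `4^-L` per strand, i.e. `2 * 4^-L` counting both strands; the
#' density of a set is the sum over its members.  An optional GC content
#' re-weights each recognition sequence by its base composition (offered
#' for exploration; the headline burden figures use the uniform model).
#'
#' @param recognition_lengths Integer vector of recognition lengths, or a
#'   character vector of recognition sequences (required when `gc` is not
#'   0.5).
#' @param gc GC content of the background model (default 0.5).
#' @param both_strands Count both strands (default TRUE)?
#' @return Expected sites per bp.
#' @export
site_density <- function(recognition_lengths, gc = 0.5, both_strands = TRUE) {
  strand_factor <- if (both_strands) 2 else 1
  if (is.numeric(recognition_lengths)) {
    if (gc != 0.5)
      stop("GC-weighted densities need recognition sequences, not lengths",
           call. = FALSE)
    return(strand_factor * sum(4^(-recognition_lengths)))
  }
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  strand_factor * sum(vapply(recognition_lengths, function(r) {
    prod(p[strsplit(toupper(r), "")[[1]]])
  }, numeric(1)))
}

#' Domestication-burden reduction between two enzyme sets
#'
#' The percent reduction in expected forbidden-site density when `new_set`
#' replaces `reference_set`: `100 * (1 - density(new) / density(ref))`.
#' With the Mobius set {6, 7} (one 6-bp and one 7-bp cutter) the reduction
#' is 58.33% against three 6-bp cutters and 37.5% against two 6-bp
#' cutters.  The ratio is invariant to the both-strands factor.
#'
#' @param new_set,reference_set Recognition lengths (or sequences) of the
#'   two enzyme sets.
#' @param gc Background GC content (default 0.5, the uniform model).
#' @return Percentage reduction.
#' @examples
#' burden_reduction(c(6, 7), c(6, 6, 6))  # 58.33...
#' burden_reduction(c(6, 7), c(6, 6))     # 37.5
#' @export
burden_reduction <- function(new_set, reference_set, gc = 0.5) {
  if (!length(new_set) || !length(reference_set))
    stop("enzyme sets must be non-empty", call. = FALSE)
  dref <- site_density(reference_set, gc = gc)
  if (dref <= 0) stop("reference set has zero site density", call. = FALSE)
  100 * (1 - site_density(new_set, gc = gc) / dref)
}

## --- synonymous-codon editing ---------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

## Relative codon usage (frequency per thousand, E. coli K-12 convention);
## used only as a deterministic tie-break between synonymous candidates.
CODON_USAGE <- c(
  TTT = 22.1, TTC = 16.0, TTA = 14.3, TTG = 13.0, CTT = 11.9, CTC = 10.2,
  CTA =  4.2, CTG = 46.9, ATT = 29.8, ATC = 23.7, ATA =  6.8, ATG = 26.4,
  GTT = 16.8, GTC = 11.7, GTA = 11.5, GTG = 26.4, TCT =  5.7, TCC =  5.5,
  TCA =  7.8, TCG =  8.0, CCT =  8.4, CCC =  6.4, CCA =  6.6, CCG = 26.7,
  ACT =  8.0, ACC = 22.8, ACA =  6.4, ACG = 11.5, GCT = 10.7, GCC = 31.6,
  GCA = 21.1, GCG = 38.5, TAT = 16.8, TAC = 14.6, TAA =  1.8, TAG =  0.0,
  CAT = 15.8, CAC = 13.1, CAA = 12.1, CAG = 27.7, AAT = 21.9, AAC = 24.4,
  AAA = 33.2, AAG = 12.1, GAT = 37.9, GAC = 20.5, GAA = 43.7, GAG = 18.4,
  TGT =  5.9, TGC =  8.0, TGA =  1.0, TGG = 13.9, CGT = 21.1, CGC = 26.0,
  CGA =  4.3, CGG =  4.1, AGT =  7.2, AGC = 16.6, AGA =  1.4, AGG =  1.6,
  GGT = 21.3, GGC = 33.4, GGA =  9.2, GGG =  8.6)

#' Translate a coding sequence
#' @param seq Nucleotide string whose length is a multiple of 3.
#' @return Amino-acid string (stops as `*`).
#' @export
translate_cds <- function(seq) {
  stopifnot(nchar(seq) %% 3 == 0)
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

forbidden_hits <- function(seq, forbidden) {
  m <- dna_molecule("scan", seq, "linear")
  do.call(rbind, lapply(forbidden, function(e) find_sites(m, e)))
}

#' Domesticate a coding sequence by synonymous codon substitution
#'
#' Removes every forbidden recognition site from the coding span of `m`
#' with single-codon synonymous edits, never altering the encoded protein
#' and never creating new forbidden sites.  After each applied edit the
#' sequence is re-scanned (fix-point loop), so overlapping sites are
#' handled.  The edit choice is deterministic: among synonymous
#' replacement codons that break the targeted site without creating a new
#' one, prefer (1) a change only at the codon's third position, then
#' (2) the highest-usage codon per the bundled usage table, then (3) the
#' lowest codon position.
#'
#' @param m A `dna_molecule` (linear CDS; the coding span starts at
#'   `frame_offset` and must be a multiple of 3 long).
#' @param frame_offset 0-based offset of the first codon.
#' @param forbidden Enzymes whose sites must be removed (default AarI and
#'   BsaI).
#' @return List with `edits` (each: `codon_index` 0-based, `position`
#'   0-based nt position, `original`, `replacement`, `broken_site`) and
#'   `molecule`, the edited `dna_molecule`.  Errors if a site cannot be
#'   broken synonymously (e.g. spans of Met/Trp codons), naming the span.
#' @examples
#' res <- domesticate_cds(dna_molecule("cds", "ATGGGTCTCTAA"))
#' res$edits[[1]]$original
#' @export
domesticate_cds <- function(m, frame_offset = 0L, forbidden = mobius_enzymes()) {
  stopifnot(is(m, "dna_molecule"))
  seq <- m$sequence
  frame_offset <- as.integer(frame_offset)
  span_len <- nchar(seq) - frame_offset
  if (span_len %% 3 != 0)
    stop("coding span (length - frame_offset) must be divisible by 3",
         call. = FALSE)
  syn <- codon_table()
  gc_map <- Biostrings::GENETIC_CODE
  forbidden <- lapply(forbidden, get_enzyme)
  enz_by_name <- setNames(forbidden,
                          vapply(forbidden, function(e) e$name, ""))
  edits <- list()
  max_iter <- nchar(seq)  # fix-point loop bound

  for (iter in seq_len(max_iter)) {
    hits <- forbidden_hits(seq, forbidden)
    if (is.null(hits) || !nrow(hits)) break
    hits <- hits[order(hits$position), , drop = FALSE]
    hit <- hits[1L, ]
    lr <- nchar(enz_by_name[[hit$enzyme]]$recognition)
    old_positions <- paste(hits$enzyme, hits$position, hits$strand)

    ## codons overlapping the recognition footprint
    c_first <- (hit$position - frame_offset) %/% 3L
    c_last <- (hit$position + lr - 1L - frame_offset) %/% 3L
    c_first <- max(c_first, 0L)
    c_last <- min(c_last, span_len %/% 3L - 1L)

    candidates <- list()
    for (ci in c_first:c_last) {
      at <- frame_offset + 3L * ci
      orig <- substr(seq, at + 1L, at + 3L)
      for (alt in setdiff(syn[[unname(gc_map[orig])]], orig)) {
        cand_seq <- paste0(substr(seq, 1L, at), alt,
                           substr(seq, at + 4L, nchar(seq)))
        cand_hits <- forbidden_hits(cand_seq, forbidden)
        cand_positions <- if (is.null(cand_hits)) character() else
          paste(cand_hits$enzyme, cand_hits$position, cand_hits$strand)
        broke <- !(paste(hit$enzyme, hit$position, hit$strand) %in% cand_positions)
        no_new <- all(cand_positions %in% old_positions)
        if (broke && no_new) {
          third_only <- substr(orig, 1, 2) == substr(alt, 1, 2)
          candidates[[length(candidates) + 1L]] <-
            list(codon_index = ci, position = at, original = orig,
                 replacement = alt, seq = cand_seq,
                 third_only = third_only, usage = CODON_USAGE[[alt]])
        }
      }
    }
    if (!length(candidates))
      stop(sprintf(
        "unresolvable %s site at positions %d-%d of '%s': no synonymous single-codon edit breaks it",
        hit$enzyme, hit$position, hit$position + lr - 1L, m$id), call. = FALSE)
    ord <- order(!vapply(candidates, `[[`, logical(1), "third_only"),
                 -vapply(candidates, `[[`, numeric(1), "usage"),
                 vapply(candidates, `[[`, numeric(1), "position"))
    best <- candidates[[ord[1L]]]
    seq <- best$seq
    edits[[length(edits) + 1L]] <-
      list(codon_index = best$codon_index, position = best$position,
           original = best$original, replacement = best$replacement,
           broken_site = list(enzyme = hit$enzyme, position = hit$position,
                              strand = hit$strand))
  }
  out <- m
  out$sequence <- seq
  list(edits = edits, molecule = out)
}
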