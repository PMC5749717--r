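#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

## Reverse complement of a bare string (vectorised over one string only).
rc <- function(x) {
  if (!nzchar(x)) return(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

check_alphabet <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence of '", id, "' must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop("sequence of '", id, "' contains characters outside the A/C/G/T alphabet ",
         "(degenerate IUPAC codes are rejected, not expanded)", call. = FALSE)
  invisible(TRUE)
}

empty_features <- function() {
  data.frame(label = character(), type = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

as_features <- function(features) {
  if (is.null(features)) return(empty_features())
  stopifnot(is.data.frame(features))
  for (col in c("label", "type", "start", "end", "strand"))
    if (is.null(features[[col]]))
      features[[col]] <- if (col %in% c("start", "end")) integer() else character()
  features[, c("label", "type", "start", "end", "strand"), drop = FALSE]
}

#' Create a double-stranded DNA molecule
#'
#' The universal sequence container of the package: the top strand 5'->3'
#' over the strict A/C/G/T alphabet, a linear or circular topology, and an
#' optional feature table.  All coordinates are 0-based and half-open on the
#' top strand; for circular molecules position arithmetic is modulo length,
#' with the origin sitting between positions `length - 1` and `0`.
#'
#' @param id Character label for the molecule.
#' @param sequence Top-strand nucleotide string (upper or lower case).
#' @param topology `"linear"` or `"circular"`.
#' @param features Optional `data.frame` with columns `label`, `type`,
#'   `start`, `end` (0-based, half-open) and `strand` (`"+"`/`"-"`).
#' @return An object of class `dna_molecule`.
#' @examples
#' m <- dna_molecule("demo", "ACGTACGT", "circular")
#' seq_length(m)
#' @export
dna_molecule <- function(id, sequence, topology = c("linear", "circular"),
                         features = NULL) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  check_alphabet(sequence, id)
  feats <- as_features(features)
  if (nrow(feats) && any(feats$start < 0L | feats$end > nchar(sequence) | feats$end < feats$start))
    stop("feature coordinates out of range for '", id, "'", call. = FALSE)
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = feats),
            class = "dna_molecule")
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule> %s: %d bp, %s, %d feature(s)\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features)))
  invisible(x)
}

#' Length of a DNA molecule in base pairs
#' @param m A `dna_molecule`.
#' @return Integer length.
#' @export
seq_length <- function(m) nchar(m$sequence)

is_circular <- function(m) identical(m$topology, "circular")

#' Reverse complement of a DNA molecule
#'
#' Returns the Watson-Crick reverse complement; features are carried over
#' with mirrored coordinates and flipped strands, topology is preserved.
#'
#' @param m A `dna_molecule`.
#' @return A `dna_molecule`.
#' @examples
#' reverse_complement(dna_molecule("x", "CACCTGC"))$sequence  # "GCAGGTG"
#' @export
reverse_complement <- function(m) {
  stopifnot(is(m, "dna_molecule"))
  len <- seq_length(m)
  feats <- m$features
  if (nrow(feats)) {
    new_start <- len - feats$end
    new_end <- len - feats$start
    feats$start <- new_start
    feats$end <- new_end
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
    feats <- feats[order(feats$start), , drop = FALSE]
    rownames(feats) <- NULL
  }
  dna_molecule(m$id, rc(m$sequence), m$topology, feats)
}

#' Define a Type IIS restriction enzyme
#'
#' A Type IIS enzyme cuts downstream of its (non-palindromic) recognition
#' sequence: the top strand is cut `spacer` nucleotides after the
#' recognition end and the bottom strand `spacer + overhang_len`
#' nucleotides after, leaving a 4-nt 5' extension for both built-ins.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence on the strand the enzyme reads.
#' @param spacer Nucleotides between recognition end and top-strand cut.
#' @param overhang_len Length of the 5' extension produced (4 for both
#'   built-ins).
#' @return An object of class `type_iis_enzyme`.
#' @seealso [mobius_enzymes()] for the built-in AarI and BsaI definitions.
#' @export
type_iis_enzyme <- function(name, recognition, spacer, overhang_len = 4L) {
  recognition <- toupper(recognition)
  check_alphabet(recognition, name)
  spacer <- as.integer(spacer)
  overhang_len <- as.integer(overhang_len)
  if (spacer < 0L) stop("spacer must be >= 0", call. = FALSE)
  if (overhang_len < 1L) stop("overhang_len must be >= 1", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 spacer = spacer, overhang_len = overhang_len),
            class = "type_iis_enzyme")
}

#' Built-in Mobius Assembly enzymes
#'
#' AarI is the rare 7-bp cutter CACCTGC(4/8); BsaI is the standard 6-bp
#' cutter GGTCTC(1/5).  The BsaI geometry is not vendor-specific lore:
#' it is the fixed constant used throughout the modular-cloning
#' literature.  Both leave 4-nt 5' extensions.
#'
#' @return Named list of `type_iis_enzyme` objects (`AarI`, `BsaI`).
#' @examples
#' mobius_enzymes()$AarI$recognition
#' @export
mobius_enzymes <- function() {
  list(AarI = type_iis_enzyme("AarI", "CACCTGC", 4L, 4L),
       BsaI = type_iis_enzyme("BsaI", "GGTCTC", 1L, 4L))
}

#' Look up an enzyme by name
#' @param x An enzyme name (`"AarI"`/`"BsaI"`), or a `type_iis_enzyme`
#'   passed through unchanged.
#' @param extra Optional named list of additional enzyme definitions.
#' @return A `type_iis_enzyme`.
#' @export
get_enzyme <- function(x, extra = NULL) {
  if (is(x, "type_iis_enzyme")) return(x)
  reg <- c(mobius_enzymes(), extra)
  if (!x %in% names(reg))
    stop("unknown enzyme '", x, "'", call. = FALSE)
  reg[[x]]
}

## All fixed-string match starts (0-based) of pattern in subject.
match_starts <- function(subject, pattern) {
  if (nchar(subject) < nchar(pattern)) return(integer())
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m) - 1L
}

#' Find Type IIS recognition sites on both strands
#'
#' Reports every occurrence of the enzyme's recognition sequence on either
#' strand, together with the cut coordinates it implies.  For a `+` hit at
#' 0-based position `p`, `cut_top = p + |recognition| + spacer` and
#' `cut_bottom = cut_top + overhang_len`; `-` hits (recognition on the
#' bottom strand, reported at the 0-based start of its top-strand
#' footprint) mirror that arithmetic, cutting upstream.  On circular
#' molecules sites spanning the origin are found and all cut coordinates
#' are reduced modulo length.
#'
#' @param m A `dna_molecule`.
#' @param enzyme A `type_iis_enzyme` or built-in enzyme name.
#' @return `data.frame` with columns `enzyme`, `position`, `strand`,
#'   `cut_top`, `cut_bottom`, sorted by `position`.
#' @export
find_sites <- function(m, enzyme) {
  enzyme <- get_enzyme(enzyme)
  seq <- m$sequence
  len <- nchar(seq)
  pat_f <- enzyme$recognition
  pat_r <- rc(enzyme$recognition)
  lr <- nchar(pat_f)
  subject <- if (is_circular(m) && len >= lr)
    paste0(seq, substr(seq, 1L, lr - 1L)) else seq

  pos_f <- match_starts(subject, pat_f)
  pos_r <- match_starts(subject, pat_r)
  pos_f <- pos_f[pos_f < len]
  pos_r <- pos_r[pos_r < len]

  o <- enzyme$overhang_len
  s <- enzyme$spacer
  hit <- function(pos, strand) {
    if (!length(pos)) return(NULL)
    ct <- if (strand == "+") pos + lr + s else pos - s - o
    data.frame(enzyme = enzyme$name, position = pos, strand = strand,
               cut_top = ct, cut_bottom = ct + o, stringsAsFactors = FALSE)
  }
  res <- rbind(hit(pos_f, "+"), hit(pos_r, "-"))
  if (is.null(res))
    return(data.frame(enzyme = character(), position = integer(),
                      strand = character(), cut_top = integer(),
                      cut_bottom = integer(), stringsAsFactors = FALSE))
  if (is_circular(m)) {
    res$cut_top <- res$cut_top %% len
    res$cut_bottom <- res$cut_top + o
  }
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Circular substring [a, b) of seq, b may exceed length (wraps).
circ_substr <- function(seq, a, b) {
  len <- nchar(seq)
  a <- a %% len
  width <- b - a
  if (width <= 0) return("")
  substr(paste0(seq, substr(seq, 1L, min(len, width))), a + 1L, a + width)
}

## Features of the circular/linear parent fully contained in [a, a + width),
## reported relative to a.
features_in_window <- function(m, a, width) {
  feats <- m$features
  if (!nrow(feats)) return(empty_features())
  len <- seq_length(m)
  keep <- list()
  for (i in seq_len(nrow(feats))) {
    s <- feats$start[i]; e <- feats$end[i]
    ## candidate placements relative to window start (circular: two shifts)
    shifts <- if (is_circular(m)) c(0L, len) else 0L
    for (sh in shifts) {
      rs <- s - a + sh
      re <- e - a + sh
      if (rs >= 0L && re <= width) {
        f <- feats[i, , drop = FALSE]
        f$start <- rs; f$end <- re
        keep[[length(keep) + 1L]] <- f
        break
      }
    }
  }
  if (!length(keep)) return(empty_features())
  out <- do.call(rbind, keep)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Count recognition sites (both strands) intact within the double-stranded
## region of a fragment core. The terminal single-stranded extensions (one
## strand missing on each side) cannot be bound by the enzyme.
count_intact <- function(core, left_len, right_len, enzyme) {
  enzyme <- get_enzyme(enzyme)
  ds <- substr(core, left_len + 1L, nchar(core) - right_len)
  length(match_starts(ds, enzyme$recognition)) +
    length(match_starts(ds, rc(enzyme$recognition)))
}

new_fragment <- function(core, left, right, source, features = empty_features(),
                         enzymes = mobius_enzymes(), uncut = FALSE) {
  carries <- vapply(enzymes, function(e)
    count_intact(core, nchar(left), nchar(right), e), integer(1))
  structure(list(core = core, left_overhang = left, right_overhang = right,
                 source = source, features = features,
                 carries_sites = carries, uncut = uncut),
            class = "sticky_fragment")
}

#' @export
print.sticky_fragment <- function(x, ...) {
  cat(sprintf("<sticky_fragment> %s: %d nt [%s ... %s]%s\n", x$source,
              nchar(x$core),
              if (nzchar(x$left_overhang)) x$left_overhang else "blunt",
              if (nzchar(x$right_overhang)) x$right_overhang else "blunt",
              if (x$uncut) " (uncut)" else ""))
  invisible(x)
}

#' Digest a molecule with a Type IIS enzyme
#'
#' Cuts the molecule at every site found by [find_sites()] and returns the
#' resulting sticky-ended fragments.  Every sticky end is recorded as the
#' top-strand 4-mer spanning the cut, so two ends are ligation-compatible
#' exactly when their overhang strings are equal.  A fragment `core` runs
#' from its left cut to the end of its right overhang, i.e. it includes
#' both terminal overhang 4-mers; consequently, for a circular parent with
#' `k` cuts the `k` fragment cores satisfy
#' `sum(nchar(core) - overhang_len) == parent length`.
#'
#' A circular molecule with no sites is returned as a single fragment
#' flagged `uncut`; a linear molecule whose cut arithmetic runs off either
#' end raises a geometry error.
#'
#' @inheritParams find_sites
#' @return List of `sticky_fragment` objects.
#' @examples
#' m <- dna_molecule("demo", "AAGGTCTCTGGAGTTTT", "linear")
#' frags <- digest(m, "BsaI")
#' frags[[2]]$left_overhang  # "GGAG"
#' @export
digest <- function(m, enzyme) {
  enzyme <- get_enzyme(enzyme)
  len <- seq_length(m)
  hits <- find_sites(m, enzyme)
  o <- enzyme$overhang_len

  if (!nrow(hits)) {
    if (is_circular(m))
      return(list(new_fragment(m$sequence, "", "", m$id, m$features,
                               uncut = TRUE)))
    return(list(new_fragment(m$sequence, "", "", m$id, m$features)))
  }

  if (!is_circular(m) &&
      (any(hits$cut_top < 0L) || any(hits$cut_bottom > len)))
    stop("digest geometry error: a ", enzyme$name,
         " cut on '", m$id, "' runs off a linear end", call. = FALSE)

  cuts <- sort(unique(hits$cut_top))
  frags <- list()
  if (is_circular(m)) {
    k <- length(cuts)
    for (i in seq_len(k)) {
      a <- cuts[i]
      b <- if (i < k) cuts[i + 1L] else cuts[1L] + len
      core <- circ_substr(m$sequence, a, b + o)
      frags[[i]] <- new_fragment(core,
                                 substr(core, 1L, o),
                                 substr(core, nchar(core) - o + 1L, nchar(core)),
                                 m$id,
                                 features_in_window(m, a, b + o - a))
    }
  } else {
    bounds <- c(0L, cuts, len)
    for (i in seq_len(length(bounds) - 1L)) {
      a <- bounds[i]
      b <- bounds[i + 1L]
      right_sticky <- i < length(bounds) - 1L
      left_sticky <- i > 1L
      core_end <- if (right_sticky) b + o else b
      core <- substr(m$sequence, a + 1L, core_end)
      frags[[i]] <- new_fragment(core,
                                 if (left_sticky) substr(core, 1L, o) else "",
                                 if (right_sticky) substr(core, nchar(core) - o + 1L,
                                                          nchar(core)) else "",
                                 m$id,
                                 features_in_window(m, a, core_end - a))
    }
  }
  frags
}

## Flip a fragment to its reverse-complement orientation. Under the
## top-strand-token convention the new left overhang is the reverse
## complement of the old right overhang.
flip_fragment <- function(f) {
  n <- nchar(f$core)
  core <- rc(f$core)
  feats <- f$features
  if (nrow(feats)) {
    s <- n - feats$end
    e <- n - feats$start
    feats$start <- s; feats$end <- e
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
    feats <- feats[order(feats$start), , drop = FALSE]
    rownames(feats) <- NULL
  }
  out <- f
  out$core <- core
  out$left_overhang <- rc(f$right_overhang)
  out$right_overhang <- rc(f$left_overhang)
  out$features <- feats
  out
}

## Canonical rotation of a circular sequence (lexicographically smallest
## rotation of the sequence or its reverse complement) -- used to compare
## circular molecules irrespective of origin choice.
canonical_rotation <- function(seq) {
  len <- nchar(seq)
  best <- NULL
  for (s in c(seq, rc(seq))) {
    dd <- paste0(s, s)
    for (i in 0:(len - 1L)) {
      cand <- substr(dd, i + 1L, i + len)
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}
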