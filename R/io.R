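#' Read DNA molecules from a FASTA file
#'
#' FASTA records default to linear topology; a `[circular]` tag anywhere in
#' the description line marks the record circular (the tag is stripped from
#' the id).  Sequences must be strict A/C/G/T.
#'
#' @param path Path to a FASTA file.
#' @return List of `dna_molecule` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file '", path, "'", call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("empty FASTA file '", path, "'", call. = FALSE)
  lapply(seq_along(set), function(i) {
    desc <- names(set)[i]
    circ <- grepl("\\[circular\\]", desc)
    id <- trimws(sub("\\[circular\\]", "", desc))
    dna_molecule(id, as.character(set[[i]]),
                 if (circ) "circular" else "linear")
  })
}

#' Write DNA molecules to a FASTA file
#'
#' Circular molecules get a `[circular]` description tag so that
#' [read_fasta()] round-trips topology.
#'
#' @param molecules A `dna_molecule` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(molecules, path) {
  if (is(molecules, "dna_molecule")) molecules <- list(molecules)
  seqs <- Biostrings::DNAStringSet(vapply(molecules, function(m) m$sequence, ""))
  names(seqs) <- vapply(molecules, function(m)
    if (is_circular(m)) paste(m$id, "[circular]") else m$id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

genbank_feature_key <- function(type) {
  switch(type,
         marker = "CDS", payload = "CDS", part = "misc_feature",
         resistance = "CDS", promoter = "promoter",
         terminator = "terminator", primer = "primer_bind",
         linker = "misc_feature", "misc_feature")
}

#' Write a DNA molecule as a GenBank flat file
#'
#' A deliberately small GenBank dialect: topology on the LOCUS line
#' (`linear`/`circular`), features with 1-based inclusive locations
#' (`complement(...)` for minus-strand features), a `/label` qualifier and
#' a `/note="mobius:type=..."` qualifier carrying the package's feature
#' type, and a standard ORIGIN block.  [read_genbank()] round-trips
#' everything it writes.
#'
#' @param m A `dna_molecule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(m, path) {
  stopifnot(is(m, "dna_molecule"))
  len <- seq_length(m)
  lines <- character()
  lines <- c(lines, sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                            gsub("\\s+", "_", m$id), len, m$topology,
                            format(Sys.Date(), "%d-%b-%Y")))
  lines <- c(lines, sprintf("DEFINITION  %s.", m$id))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  feats <- m$features
  if (nrow(feats)) {
    for (i in seq_len(nrow(feats))) {
      loc <- sprintf("%d..%d", feats$start[i] + 1L, feats$end[i])
      if (feats$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      key <- genbank_feature_key(feats$type[i])
      lines <- c(lines,
                 sprintf("     %-15s %s", key, loc),
                 sprintf("                     /label=\"%s\"", feats$label[i]),
                 sprintf("                     /note=\"mobius:type=%s\"", feats$type[i]))
    }
  }
  lines <- c(lines, "ORIGIN")
  seq <- tolower(m$sequence)
  for (off in seq(1L, len, by = 60L)) {
    chunk <- substr(seq, off, min(off + 59L, len))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Parses the dialect written by [write_genbank()] (and the common subset
#' of editor-produced files): LOCUS topology token, simple
#' `start..end` / `complement(start..end)` feature locations with `/label`
#' and `/note` qualifiers, and the ORIGIN sequence block.
#'
#' @param path Path to a GenBank file.
#' @return A `dna_molecule`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("'", path, "' has no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("'", path, "' has no ORIGIN block", call. = FALSE)
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(feat_at)) {
    block <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    cur <- NULL
    flush <- function(cur, feats) {
      if (is.null(cur)) return(feats)
      rbind(feats, data.frame(label = cur$label, type = cur$type,
                              start = cur$start, end = cur$end,
                              strand = cur$strand, stringsAsFactors = FALSE))
    }
    for (ln in block) {
      if (grepl("^     \\S", ln)) {
        feats <- flush(cur, feats)
        loc <- trimws(sub("^     \\S+\\s+", "", ln))
        strand <- if (grepl("^complement", loc)) "-" else "+"
        nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
        cur <- list(label = "", type = "misc",
                    start = as.integer(nums[1]) - 1L,
                    end = as.integer(nums[2]), strand = strand)
      } else if (!is.null(cur) && grepl("/label=", ln)) {
        cur$label <- gsub("\"", "", sub(".*?/label=", "", trimws(ln)))
      } else if (!is.null(cur) && grepl("/note=\"mobius:type=", ln)) {
        cur$type <- gsub("\"", "", sub(".*?mobius:type=", "", trimws(ln)))
      }
    }
    feats <- flush(cur, feats)
  }
  dna_molecule(id, sequence, topology, feats)
}
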