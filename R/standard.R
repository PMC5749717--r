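## The Mobius Assembly routing standard as data.
##
## Naming: Greek vector letters are ASCII-aliased in all machine
## interfaces (G for Gamma, D for Delta); display names keep the Greek
## letters.

GREEK <- c(A = "A", B = "B", G = "Γ", D = "Δ")
POSITION_LETTERS <- c("A", "B", "G", "D")

## Level 1 outer overhangs (AarI release), per vector. The 3' overhang of
## vector k equals the 5' overhang of vector k+1, which is what chains up
## to four single-TU cassettes head-to-tail in a Level 2 reaction.
L1_OUTER <- list(A = c("GGAG", "CAGA"),
                 B = c("CAGA", "GTCA"),
                 G = c("GTCA", "CTTG"),
                 D = c("CTTG", "CGCT"))
L1_INNER <- c("GGAG", "CGCT")      # BsaI acceptance, all Level 1 vectors
L2_INNER <- c("GGAG", "ACCC")      # AarI acceptance, all Level 2 vectors
L2_OUTER5 <- c(A = "GGAG", B = "CAGA", G = "GTCA", D = "CTTG")
MUAV_FUSION <- c("CTCT", "TGAG")   # AarI acceptance of the universal acceptor

normalize_vector_name <- function(name) {
  x <- toupper(name)
  x <- chartr("ΓΔ", "GD", x)
  x <- sub("^L([12])[- ]?", "L\\1-", x)
  if (identical(x, "MUAV")) x <- "mUAV"
  x
}

#' Vector specification of the Mobius Assembly standard
#'
#' Returns the immutable standard entry for one of the nine acceptor
#' vectors: the universal acceptor `mUAV`, the four Level 1 vectors
#' (`L1-A`, `L1-B`, `L1-G`, `L1-D`) and the four Level 2 vectors (`L2-A`
#' ... `L2-D`).  Greek letters are accepted as aliases for `G`/`D`.
#'
#' Level 0 (mUAV) and Level 2 vectors accept inserts via AarI and release
#' their finished cassette via BsaI; Level 1 vectors do the reverse.  The
#' dropout markers are amilCP (purple), spisPink (magenta) and sfGFP
#' (yellow) respectively, and resistance/backbone pairs are
#' chloramphenicol/pSB1C3 (mUAV, Level 2) and kanamycin/pSB1K3 (Level 1).
#'
#' @param name Vector name.
#' @return List with fields `name`, `display_name`, `level`,
#'   `acceptance_enzyme`, `release_enzyme`, `inner_overhangs`,
#'   `outer_overhangs`, `dropout_marker`, `resistance`, `backbone_origin`.
#' @examples
#' vector_spec("L1-A")$inner_overhangs
#' vector_spec("L2-Γ")$dropout_marker
#' @export
vector_spec <- function(name) {
  nm <- normalize_vector_name(name)
  if (identical(nm, "mUAV")) {
    return(list(name = "mUAV", display_name = "mUAV", level = 0L,
                acceptance_enzyme = "AarI", release_enzyme = "BsaI",
                inner_overhangs = MUAV_FUSION,
                outer_overhangs = MUAV_FUSION,
                dropout_marker = "amilCP", resistance = "chloramphenicol",
                backbone_origin = "pSB1C3"))
  }
  m <- regmatches(nm, regexec("^L([12])-([ABGD])$", nm))[[1]]
  if (length(m) != 3L) stop("unknown vector name '", name, "'", call. = FALSE)
  level <- as.integer(m[2])
  pos <- m[3]
  display <- sprintf("L%d-%s", level, GREEK[[pos]])
  if (level == 1L) {
    list(name = nm, display_name = display, level = 1L,
         acceptance_enzyme = "BsaI", release_enzyme = "AarI",
         inner_overhangs = L1_INNER,
         outer_overhangs = L1_OUTER[[pos]],
         dropout_marker = "spisPink", resistance = "kanamycin",
         backbone_origin = "pSB1K3")
  } else {
    list(name = nm, display_name = display, level = 2L,
         acceptance_enzyme = "AarI", release_enzyme = "BsaI",
         inner_overhangs = L2_INNER,
         outer_overhangs = c(L2_OUTER5[[pos]], NA_character_),
         dropout_marker = "sfGFP", resistance = "chloramphenicol",
         backbone_origin = "pSB1C3")
  }
}

LINKERS <- list(
  `4A` = list(kind = "end_to_end",    upstream = "CGCT", payload = "CAGA"),
  `4B` = list(kind = "end_to_end",    upstream = "CGCT", payload = "GTCA"),
  `4G` = list(kind = "end_to_end",    upstream = "CGCT", payload = "CTTG"),
  `4D` = list(kind = "end_to_end",    upstream = "CGCT", payload = "CGCT"),
  M1   = list(kind = "middle_to_end", upstream = "CAGA", payload = "CGCT"),
  M2   = list(kind = "middle_to_end", upstream = "GTCA", payload = "CGCT"),
  M3   = list(kind = "middle_to_end", upstream = "CTTG", payload = "CGCT"))

normalize_linker_name <- function(name) {
  x <- toupper(name)
  x <- chartr("ΓΔ", "GD", x)
  if (x %in% c("1", "2", "3")) x <- paste0("M", x)
  x
}

#' Linker specification of an Auxiliary Plasmid
#'
#' The seven Auxiliary Plasmids donate 50-bp linkers that close a Level 2
#' chain of one to four Level 1 cassettes.  Each linker carries three
#' overhangs: the upstream overhang annealing to the last cassette in the
#' chain, an internal payload overhang exposed only on later BsaI release
#' of the finished Level 2 cassette, and the common downstream overhang
#' ACCC annealing to the Level 2 vector backbone.
#'
#' End-to-End linkers `4A`/`4B`/`4G`/`4D` close full four-cassette chains
#' (upstream always CGCT); Middle-to-End linkers `M1`/`M2`/`M3` close
#' one-, two- or three-cassette chains and always provide the terminal
#' CGCT payload needed to clone the product back into Level 1.
#'
#' @param name Linker name (`"4A"`..`"4D"`, `"M1"`..`"M3"`; Greek letters
#'   and bare `"1"`/`"2"`/`"3"` accepted).
#' @return List with fields `name`, `kind`, `upstream_overhang`,
#'   `payload_overhang`, `downstream_overhang`, `length`.
#' @examples
#' linker_spec("4A")  # CGCT / CAGA / ACCC
#' @export
linker_spec <- function(name) {
  nm <- normalize_linker_name(name)
  if (!nm %in% names(LINKERS))
    stop("unknown Auxiliary Plasmid / linker name '", name, "'", call. = FALSE)
  l <- LINKERS[[nm]]
  list(name = nm, kind = l$kind, upstream_overhang = l$upstream,
       payload_overhang = l$payload, downstream_overhang = "ACCC",
       length = 50L)
}

#' All seven standard linker names
#' @return Character vector.
#' @export
linker_names <- function() names(LINKERS)

## Standard part-junction overhangs. The promoter/CDS/terminator internal
## junctions default to the MoClo/Phytobrick convention (AATG at the start
## codon, GCTT after the stop); they are configurable because the standard
## only fixes the TU boundaries GGAG/CGCT.
DEFAULT_PART_OVERHANGS <- data.frame(
  role = c("promoter", "CDS", "terminator", "custom"),
  left = c("GGAG", "AATG", "GCTT", "GGAG"),
  right = c("AATG", "GCTT", "CGCT", "CGCT"),
  frame_sensitive = c(FALSE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE)

#' Standard part-type overhang table
#'
#' @param role Optional role name; if given, the single matching row is
#'   returned as a list.
#' @param table Overhang table to use (override to adopt another internal
#'   junction convention; TU boundaries must stay GGAG/CGCT).
#' @return Data frame of roles, or a list for one role.
#' @export
part_type_spec <- function(role = NULL, table = DEFAULT_PART_OVERHANGS) {
  if (is.null(role)) return(table)
  row <- table[table$role == role, , drop = FALSE]
  if (!nrow(row)) stop("unknown part role '", role, "'", call. = FALSE)
  as.list(row[1L, ])
}

#' Validate that a chain of parts forms a transcriptional unit
#'
#' A chain of standard parts is a valid TU when consecutive overhangs
#' match, the chain starts with GGAG and ends with CGCT.
#'
#' @param parts Character vector of role names, or a data frame with
#'   `left`/`right` overhang columns.
#' @param table Part-overhang table (see [part_type_spec()]).
#' @return List with `valid` flag and, when invalid, `first_mismatch`
#'   (0-based junction index; 0 means the chain start) and `detail`.
#' @examples
#' validate_tu_chain(c("promoter", "CDS", "terminator"))$valid
#' @export
validate_tu_chain <- function(parts, table = DEFAULT_PART_OVERHANGS) {
  if (is.character(parts)) {
    if (!length(parts)) stop("empty part chain", call. = FALSE)
    rows <- lapply(parts, part_type_spec, table = table)
    left <- vapply(rows, function(r) r$left, "")
    right <- vapply(rows, function(r) r$right, "")
  } else {
    stopifnot(is.data.frame(parts), nrow(parts) > 0)
    left <- parts$left; right <- parts$right
  }
  if (left[1] != "GGAG")
    return(list(valid = FALSE, first_mismatch = 0L,
                detail = sprintf("chain starts %s, expected GGAG", left[1])))
  n <- length(left)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    if (right[i] != left[i + 1L])
      return(list(valid = FALSE, first_mismatch = i,
                  detail = sprintf("junction %d: %s != %s", i, right[i], left[i + 1L])))
  }
  if (right[n] != "CGCT")
    return(list(valid = FALSE, first_mismatch = n,
                detail = sprintf("chain ends %s, expected CGCT", right[n])))
  list(valid = TRUE, first_mismatch = NA_integer_, detail = "ok")
}

#' The complete Mobius routing standard
#'
#' Bundles every constant of the standard -- vector specs, linker specs,
#' part overhang defaults and the junction routing table -- into one list,
#' exportable as a single YAML document so alternative overhang standards
#' can be swapped in without code change.
#'
#' @return Nested list.
#' @export
mobius_standard <- function() {
  vecs <- c("mUAV", paste0("L1-", POSITION_LETTERS), paste0("L2-", POSITION_LETTERS))
  list(
    vectors = setNames(lapply(vecs, vector_spec), vecs),
    linkers = setNames(lapply(names(LINKERS), linker_spec), names(LINKERS)),
    part_overhangs = DEFAULT_PART_OVERHANGS,
    routing = list(l1_outer = L1_OUTER, l1_inner = L1_INNER,
                   l2_inner = L2_INNER, l2_outer5 = as.list(L2_OUTER5),
                   muav_fusion = MUAV_FUSION),
    enzymes = lapply(mobius_enzymes(), unclass))
}

#' Write the routing standard to a YAML file
#' @param path Output path.
#' @param standard Standard list (defaults to the built-in standard).
#' @return `path`, invisibly.
#' @export
write_standard <- function(path, standard = mobius_standard()) {
  yaml::write_yaml(standard, path)
  invisible(path)
}

#' Read a routing standard from a YAML file
#' @param path Path written by [write_standard()].
#' @return Nested list in the layout of [mobius_standard()].
#' @export
read_standard <- function(path) {
  std <- yaml::read_yaml(path)
  if (is.list(std$part_overhangs))
    std$part_overhangs <- as.data.frame(std$part_overhangs,
                                        stringsAsFactors = FALSE)
  std
}
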