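#' Assembly capacity of a cloning tier
#'
#' The number of transcriptional units a construct can hold after tier
#' `n` of the two-level recursion follows the geometric law
#' `a_n = a_1 * r^(n-1)` with `a_1 = 1` and `r = 4`: 1, 4, 16, 64, ...
#'
#' @param tier Integer tier index, >= 1.
#' @return Integer capacity.
#' @examples
#' capacity(3)  # 16
#' @export
capacity <- function(tier) {
  tier <- as.integer(tier)
  if (any(is.na(tier)) || any(tier < 1L))
    stop("tier must be an integer >= 1", call. = FALSE)
  as.integer(4L^(tier - 1L))
}

new_step <- function(id, level, vector, inputs, linker = NA_character_,
                     round = NA_integer_) {
  structure(list(id = id, level = level, vector = vector, inputs = inputs,
                 linker = linker, round = round),
            class = "assembly_step")
}

#' @export
print.assembly_step <- function(x, ...) {
  cat(sprintf("  [%s] round %d, Level %d, vector %s%s <- %s\n",
              x$id, x$round, x$level, x$vector,
              if (!is.na(x$linker)) paste0(" + linker ", x$linker) else "",
              paste(x$inputs, collapse = ", ")))
  invisible(x)
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(sprintf("<assembly_plan> %d TU(s), %d step(s), %d round(s)\n",
              x$n_tus, length(x$steps), x$rounds))
  for (s in x$steps) print(s)
  invisible(x)
}

## Left-packed chunk sizes: 4, 4, ..., remainder.
chunk_sizes <- function(k) {
  full <- k %/% 4L
  rem <- k %% 4L
  sizes <- rep(4L, full)
  if (rem > 0L) sizes <- c(sizes, rem)
  sizes
}

## Linker for a chunk: size < 4 -> Middle-to-End M<size>; size 4 and last
## in its Level 1 fusion group -> 4D (keeps the product terminal, i.e.
## re-clonable); otherwise the End-to-End linker matching the chunk's
## position (4A/4B/4G).
chunk_linker <- function(size, pos_in_group, group_terminal) {
  if (size < 4L) return(paste0("M", size))
  if (group_terminal) return("4D")
  paste0("4", POSITION_LETTERS[pos_in_group])
}

## Core recursion shared by plan_assembly() and extend_plan(): takes a
## vector of item step-ids (each item a Level 1 cassette whose vector
## matches its position) and appends Level 2 / Level 1 rounds until a
## single construct remains.
pack_rounds <- function(steps, items, round, next_id) {
  while (length(items) > 1L) {
    round <- round + 1L
    sizes <- chunk_sizes(length(items))
    nchunks <- length(sizes)
    chunk_ids <- character(nchunks)
    off <- 0L
    for (j in seq_len(nchunks)) {
      pos_in_group <- ((j - 1L) %% 4L) + 1L
      group_terminal <- (pos_in_group == 4L) || (j == nchunks)
      linker <- chunk_linker(sizes[j], pos_in_group, group_terminal)
      sid <- sprintf("s%02d", next_id); next_id <- next_id + 1L
      steps[[sid]] <- new_step(sid, 2L, paste0("L2-", POSITION_LETTERS[pos_in_group]),
                               items[(off + 1L):(off + sizes[j])],
                               linker = linker, round = round)
      chunk_ids[j] <- sid
      off <- off + sizes[j]
    }
    if (nchunks == 1L) { items <- chunk_ids; break }
    round <- round + 1L
    ngroups <- ceiling(nchunks / 4L)
    group_ids <- character(ngroups)
    for (g in seq_len(ngroups)) {
      members <- chunk_ids[((g - 1L) * 4L + 1L):min(g * 4L, nchunks)]
      sid <- sprintf("s%02d", next_id); next_id <- next_id + 1L
      steps[[sid]] <- new_step(sid, 1L,
                               paste0("L1-", POSITION_LETTERS[((g - 1L) %% 4L) + 1L]),
                               members, round = round)
      group_ids[g] <- sid
    }
    items <- group_ids
  }
  list(steps = steps, final = items[[1L]], rounds = round, next_id = next_id)
}

#' Plan a hierarchical multi-TU assembly
#'
#' Converts "assemble `n` ordered transcriptional units" into a
#' dependency-ordered schedule of Level 1 and Level 2 reactions.  Round 1
#' builds each TU from its standard parts in the Level 1 vector matching
#' its position (A, B, Gamma, Delta cycling).  TUs are then packed
#' left-to-right into chunks of four (one trailing remainder) for Level 2,
#' each chunk receiving the Auxiliary linker its size and position
#' dictate, and up to four Level 2 cassettes are fused back into a Level 1
#' vector; the two levels alternate until a single construct remains.
#' `n = 1` yields a Level-1-only plan, and `2 <= n <= 4` stops at the
#' single Level 2 product.
#'
#' Planning is fully deterministic.
#'
#' @param n Number of transcriptional units, >= 1.
#' @return An `assembly_plan`: list with `n_tus`, `steps` (named list of
#'   `assembly_step`), `rounds`, `final` (id of the final step) and
#'   `terminal` (always `TRUE`: every planned construct ends in CGCT and
#'   can be extended).
#' @examples
#' plan_assembly(7)   # 4 TUs + 4A in L2-A, 3 TUs + M3 in L2-B, fused in L1-A
#' @export
plan_assembly <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1", call. = FALSE)
  steps <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("s%02d", i)
    steps[[sid]] <- new_step(sid, 1L,
                             paste0("L1-", POSITION_LETTERS[((i - 1L) %% 4L) + 1L]),
                             sprintf("tu:%d", i), round = 1L)
  }
  items <- names(steps)
  packed <- pack_rounds(steps, items, 1L, n + 1L)
  structure(list(n_tus = n, steps = packed$steps, rounds = packed$rounds,
                 final = packed$final, terminal = TRUE),
            class = "assembly_plan")
}

#' Extend an existing assembly plan with additional TUs
#'
#' Reuses the existing final construct as the first item of a new round
#' and appends `extra` new TUs, mirroring the standard's ability to grow
#' an already constructed multi-TU by switching between the two cloning
#' levels.  If the existing plan ends in a Level 2 product, one Level 1
#' fusion step is added first so the construct re-enters the cycle as a
#' Level 1 cassette in vector A.
#'
#' @param existing An `assembly_plan` whose final construct is terminal
#'   (ends in CGCT; true of every plan this package produces).
#' @param extra Number of TUs to append (>= 0; 0 returns the plan
#'   unchanged).
#' @return An `assembly_plan` for `existing$n_tus + extra` TUs.
#' @examples
#' extend_plan(plan_assembly(4), 1)
#' @export
extend_plan <- function(existing, extra) {
  stopifnot(is(existing, "assembly_plan"))
  extra <- as.integer(extra)
  if (is.na(extra) || extra < 0L) stop("extra must be an integer >= 0", call. = FALSE)
  if (!isTRUE(existing$terminal))
    stop("cannot extend: existing final construct is not terminal (does not end in CGCT)",
         call. = FALSE)
  if (extra == 0L) return(existing)

  steps <- existing$steps
  round <- existing$rounds
  next_id <- length(steps) + 1L
  a <- existing$n_tus
  top <- existing$final

  if (steps[[top]]$level == 2L) {
    ## clone the finished Level 2 construct back into Level 1 vector A
    round <- round + 1L
    sid <- sprintf("s%02d", next_id); next_id <- next_id + 1L
    steps[[sid]] <- new_step(sid, 1L, "L1-A", top, round = round)
    top <- sid
  }
  items <- top
  for (t in seq_len(extra)) {
    pos <- (t %% 4L) + 1L  # item index is 1 + t; the existing cassette is item 1
    sid <- sprintf("s%02d", next_id); next_id <- next_id + 1L
    steps[[sid]] <- new_step(sid, 1L, paste0("L1-", POSITION_LETTERS[pos]),
                             sprintf("tu:%d", a + t), round = round)
    items <- c(items, sid)
  }
  packed <- pack_rounds(steps, items, round, next_id)
  structure(list(n_tus = a + extra, steps = packed$steps,
                 rounds = packed$rounds, final = packed$final,
                 terminal = TRUE),
            class = "assembly_plan")
}

plan_to_list <- function(plan) {
  list(n_tus = plan$n_tus, rounds = plan$rounds, final = plan$final,
       steps = lapply(unname(plan$steps), function(s)
         list(id = s$id, level = s$level, round = s$round, vector = s$vector,
              linker = if (is.na(s$linker)) NULL else s$linker,
              inputs = as.list(s$inputs))))
}

#' Write an assembly plan to a YAML file
#' @param plan An `assembly_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  yaml::write_yaml(plan_to_list(plan), path)
  invisible(path)
}

#' Read an assembly plan from a YAML file
#' @param path Path written by [write_plan()].
#' @return An `assembly_plan`.
#' @export
read_plan <- function(path) {
  x <- yaml::read_yaml(path)
  steps <- list()
  for (s in x$steps)
    steps[[s$id]] <- new_step(s$id, as.integer(s$level), s$vector,
                              unlist(s$inputs),
                              linker = if (is.null(s$linker)) NA_character_ else s$linker,
                              round = as.integer(s$round))
  structure(list(n_tus = as.integer(x$n_tus), steps = steps,
                 rounds = as.integer(x$rounds), final = x$final,
                 terminal = TRUE),
            class = "assembly_plan")
}

MARKER_COLOURS <- c(mUAV = "purple (amilCP)", `1` = "magenta (spisPink)",
                    `2` = "yellow (sfGFP)")

#' Render a human-readable bench sheet for a plan
#'
#' One block per reaction: destination vector, enzyme, inserts, Auxiliary
#' linker, and the colony colour that marks *failed* (dropout-retaining)
#' clones at that level.  Intended for printing next to the bench; the
#' machine-readable form is [write_plan()].
#'
#' @param plan An `assembly_plan`.
#' @return Character vector of lines.
#' @export
bench_sheet <- function(plan) {
  lines <- c(sprintf("Mobius assembly bench sheet: %d TU(s), %d reaction(s), %d round(s)",
                     plan$n_tus, length(plan$steps), plan$rounds),
             strrep("-", 64))
  for (s in plan$steps) {
    enz <- if (s$level == 1L) "BsaI" else "AarI"
    colour <- MARKER_COLOURS[[as.character(s$level)]]
    vec <- vector_spec(s$vector)
    lines <- c(lines,
               sprintf("Step %s (round %d): Level %d reaction in %s [%s]",
                       s$id, s$round, s$level, vec$display_name, enz),
               sprintf("  inserts : %s", paste(s$inputs, collapse = ", ")),
               if (!is.na(s$linker))
                 sprintf("  linker  : Auxiliary Plasmid %s", s$linker),
               sprintf("  failures: %s colonies (marker retained); correct clones are white",
                       colour))
  }
  c(lines,
    "",
    "Reaction (per standard one-pot protocol, volumes echoed as text):",
    "  10 ul total: ~100 ng acceptor, equimolar inserts, 0.5 ul T4 DNA",
    "  ligase, 1 ul ligase buffer, 0.25-0.5 ul Type IIS enzyme; for AarI",
    "  add 0.2 ul 50x oligonucleotide activator (wet-lab only, no",
    "  sequence-design consequence in silico).")
}
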