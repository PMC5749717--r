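#' Construct a one-pot Golden Gate reaction mix
#'
#' @param acceptor Circular `dna_molecule` acceptor vector (must carry a
#'   feature of type `"resistance"`, which identifies its backbone
#'   fragment after digestion).
#' @param inserts List of `dna_molecule` donors: circular plasmids or
#'   linear PCR products.
#' @param enzyme The reaction's Type IIS enzyme (name or object).
#' @param max_cycle_len Cap on fragments per circular product (default 12;
#'   concatemers/tandem repeats are outside the product model).
#' @return A `reaction_mix`.
#' @export
reaction_mix <- function(acceptor, inserts, enzyme, max_cycle_len = 12L) {
  stopifnot(is(acceptor, "dna_molecule"))
  if (is(inserts, "dna_molecule")) inserts <- list(inserts)
  if (!is_circular(acceptor))
    stop("acceptor must be circular", call. = FALSE)
  if (!any(acceptor$features$type == "resistance"))
    stop("acceptor carries no 'resistance' feature to identify its backbone",
         call. = FALSE)
  structure(list(acceptor = acceptor, inserts = inserts,
                 enzyme = get_enzyme(enzyme),
                 max_cycle_len = as.integer(max_cycle_len)),
            class = "reaction_mix")
}

is_palindromic_overhang <- function(tok) nzchar(tok) && identical(tok, rc(tok))

diagnostics <- function(products_found, failure_mode, detail = "") {
  list(products_found = products_found, failure_mode = failure_mode,
       detail = detail)
}

## Assemble the circular product molecule from an ordered list of oriented
## fragments (backbone first).  Each junction 4-mer is counted once: every
## fragment contributes its core minus the leading overhang, so the
## backbone's left overhang is supplied by the last fragment's tail.
close_cycle <- function(frags, id) {
  pieces <- vapply(frags, function(f) substr(f$core, 5L, nchar(f$core)), "")
  seq <- paste0(pieces, collapse = "")
  total <- nchar(seq)
  feats <- list()
  cum <- 0L
  for (f in frags) {
    fl <- nchar(f$core)
    if (nrow(f$features)) {
      ff <- f$features
      ff$start <- (cum - 4L + ff$start) %% total
      ff$end <- ff$start + (f$features$end - f$features$start)
      ## drop the rare feature that would wrap the arbitrary origin
      ff <- ff[ff$end <= total, , drop = FALSE]
      if (nrow(ff)) feats[[length(feats) + 1L]] <- ff
    }
    cum <- cum + fl - 4L
  }
  feats <- if (length(feats)) do.call(rbind, feats) else empty_features()
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  dna_molecule(id, seq, "circular", feats)
}

#' Simulate a one-pot Golden Gate digestion-ligation reaction
#'
#' Digests the acceptor and every insert with the reaction enzyme, then
#' enumerates circular ligation products over the overhang-matching graph:
#' fragments are directed edges labelled by their terminal 4-mers, both
#' orientations of every fragment are considered, each physical fragment
#' is used at most once per product, and every product contains exactly
#' one backbone fragment (the acceptor fragment carrying the resistance
#' feature).  A product is *valid* iff its closed circle contains zero
#' intact recognition sites of the reaction enzyme on either strand --
#' which automatically rejects re-ligation of the dropout marker, whose
#' fragment retains its sites.
#'
#' The idealised end-point model: ligase/buffer kinetics, overhang-fidelity
#' mismatches and transformation statistics are not modelled.
#'
#' @param mix A `reaction_mix` (or an acceptor, with `inserts`/`enzyme`
#'   given, for convenience).
#' @param inserts,enzyme Used only when `mix` is a bare acceptor.
#' @return List with `product` (an `assembly_product`: fields `molecule`,
#'   `fragment_order`, `valid`; or `NULL`) and `diagnostics`
#'   (`products_found`, `failure_mode` one of `none`, `no_closed_cycle`,
#'   `multiple_valid_products`, `overhang_clash`, `uncut_input`, and free
#'   text `detail`).
#' @export
simulate_one_pot <- function(mix, inserts = NULL, enzyme = NULL) {
  if (is(mix, "dna_molecule"))
    mix <- reaction_mix(mix, inserts, enzyme)
  stopifnot(is(mix, "reaction_mix"))
  enz <- mix$enzyme

  acc_frags <- digest(mix$acceptor, enz)
  if (length(acc_frags) == 1L && isTRUE(acc_frags[[1]]$uncut))
    return(list(product = NULL,
                diagnostics = diagnostics(0L, "uncut_input",
                  sprintf("acceptor '%s' has no %s site", mix$acceptor$id, enz$name))))

  res_label <- mix$acceptor$features$label[mix$acceptor$features$type == "resistance"][1]
  pool <- acc_frags
  origin <- rep("acceptor", length(acc_frags))
  for (ins in mix$inserts) {
    fr <- digest(ins, enz)
    pool <- c(pool, fr)
    origin <- c(origin, rep("insert", length(fr)))
  }

  is_backbone <- vapply(seq_along(pool), function(i)
    origin[i] == "acceptor" &&
      any(pool[[i]]$features$type == "resistance" &
            pool[[i]]$features$label == res_label), logical(1))
  if (sum(is_backbone) != 1L)
    return(list(product = NULL,
                diagnostics = diagnostics(0L, "uncut_input",
                  "could not identify a unique acceptor backbone fragment")))
  bb_idx <- which(is_backbone)

  warnings <- character()
  toks <- unique(unlist(lapply(pool, function(f)
    c(f$left_overhang, f$right_overhang))))
  pal <- Filter(is_palindromic_overhang, toks)
  if (length(pal))
    warnings <- c(warnings, sprintf(
      "fidelity warning: palindromic overhang(s) %s can self-anneal",
      paste(unique(pal), collapse = ", ")))

  ## orientation table: for each fragment, usable orientations (sticky at
  ## both ends only -- blunt ends never enter a circle)
  orient <- function(i, flipped) {
    f <- if (flipped) flip_fragment(pool[[i]]) else pool[[i]]
    list(idx = i, flipped = flipped, frag = f,
         left = f$left_overhang, right = f$right_overhang)
  }
  edges <- list()
  for (i in seq_along(pool)) {
    f <- pool[[i]]
    if (!nzchar(f$left_overhang) || !nzchar(f$right_overhang)) next
    if (i == bb_idx) {
      edges[[length(edges) + 1L]] <- orient(i, FALSE)  # backbone fixed forward
    } else {
      edges[[length(edges) + 1L]] <- orient(i, FALSE)
      edges[[length(edges) + 1L]] <- orient(i, TRUE)
    }
  }
  by_left <- split(seq_along(edges),
                   vapply(edges, function(e) e$left, ""))
  bb_edge <- which(vapply(edges, function(e) e$idx == bb_idx, logical(1)))
  if (!length(bb_edge))
    return(list(product = NULL,
                diagnostics = diagnostics(0L, "no_closed_cycle",
                  "backbone fragment has a blunt end")))

  start <- edges[[bb_edge]]
  cycles <- list()
  used <- logical(length(pool))
  path <- list(start)
  used[bb_idx] <- TRUE
  dfs <- function(tail_tok) {
    if (length(cycles) > 50L) return()  # combinatorial guard
    if (identical(tail_tok, start$left) && length(path) >= 1L) {
      cycles[[length(cycles) + 1L]] <<- path
      ## keep exploring: longer cycles through the same token may exist
    }
    if (length(path) >= mix$max_cycle_len) return()
    for (ei in by_left[[tail_tok]]) {
      e <- edges[[ei]]
      if (e$idx == bb_idx || used[e$idx]) next
      used[e$idx] <<- TRUE
      path[[length(path) + 1L]] <<- e
      dfs(e$right)
      path[[length(path)]] <<- NULL
      used[e$idx] <<- FALSE
    }
  }
  dfs(start$right)

  if (!length(cycles))
    return(list(product = NULL,
                diagnostics = diagnostics(0L, "no_closed_cycle",
                  paste(c("no circular ligation product closes", warnings),
                        collapse = "; "))))

  build <- function(cyc) {
    frags <- lapply(cyc, function(e) e$frag)
    mol <- close_cycle(frags, paste0(mix$acceptor$id, "::product"))
    order <- lapply(cyc, function(e)
      list(source = pool[[e$idx]]$source,
           orientation = if (e$flipped) "-" else "+"))
    valid <- nrow(find_sites(mol, enz)) == 0L
    structure(list(molecule = mol, fragment_order = order, valid = valid),
              class = "assembly_product")
  }
  products <- lapply(cycles, build)
  valid_products <- Filter(function(p) p$valid, products)

  ## dedupe identical molecules reached through different paths
  if (length(valid_products) > 1L) {
    keys <- vapply(valid_products, function(p) p$molecule$sequence, "")
    valid_products <- valid_products[!duplicated(keys)]
  }

  if (!length(valid_products))
    return(list(product = NULL,
                diagnostics = diagnostics(length(products), "no_closed_cycle",
                  paste(c(sprintf("%d circular candidate(s), none free of %s sites",
                                  length(products), enz$name), warnings),
                        collapse = "; "))))
  if (length(valid_products) > 1L) {
    all_left <- vapply(edges, function(e) e$left, "")
    dup <- any(duplicated(vapply(Filter(function(e) !e$flipped, edges),
                                 function(e) e$left, "")))
    mode <- if (dup) "overhang_clash" else "multiple_valid_products"
    return(list(product = NULL,
                diagnostics = diagnostics(length(valid_products), mode,
                  sprintf("%d distinct valid products", length(valid_products)))))
  }
  list(product = valid_products[[1]],
       diagnostics = diagnostics(1L, "none",
                                 paste(c("ok", warnings), collapse = "; ")))
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf("<assembly_product> %s: %d bp circular, %d fragment(s), %s\n",
              x$molecule$id, seq_length(x$molecule), length(x$fragment_order),
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Release the finished cassette from an assembly product
#'
#' Digests a valid product with its release enzyme (which must cut exactly
#' twice) and returns the insert-side fragment -- the one not carrying the
#' backbone's resistance feature -- with its release overhangs.
#'
#' @param product An `assembly_product` (or bare circular `dna_molecule`
#'   with a resistance feature).
#' @param release_enzyme Enzyme name or object.
#' @return A `sticky_fragment`.
#' @export
cassette_of <- function(product, release_enzyme) {
  mol <- if (is(product, "assembly_product")) product$molecule else product
  if (is(product, "assembly_product") && !product$valid)
    stop("cannot release a cassette from an invalid product", call. = FALSE)
  enz <- get_enzyme(release_enzyme)
  hits <- find_sites(mol, enz)
  if (nrow(hits) != 2L)
    stop("release error: ", enz$name, " cuts '", mol$id, "' ",
         nrow(hits), " time(s), expected exactly 2", call. = FALSE)
  frags <- digest(mol, enz)
  has_res <- vapply(frags, function(f)
    any(f$features$type == "resistance"), logical(1))
  if (sum(!has_res) != 1L)
    stop("release error: could not identify the insert-side fragment",
         call. = FALSE)
  frags[[which(!has_res)]]
}

#' Execute every reaction of an assembly plan on fixture plasmids
#'
#' Runs the plan's steps in dependency order through
#' [simulate_one_pot()]: round-1 steps assemble each TU's promoter, CDS
#' and terminator Level 0 plasmids into the assigned Level 1 vector;
#' Level 2 steps combine the upstream Level 1 products with the assigned
#' Auxiliary Plasmid; Level 1 fusion steps combine upstream Level 2
#' products.  Any non-clean diagnostic aborts with the failing step
#' identified.
#'
#' @param plan An `assembly_plan`.
#' @param toolkit A `mobius_toolkit` from [build_toolkit()].
#' @param cargo TU cargo as returned by [build_dummy_tu_parts()]: a list
#'   of length `plan$n_tus`, each element a list with `promoter`, `cds`,
#'   `terminator` Level 0 plasmids.
#' @param keep_intermediates Return all intermediate products too?
#' @return The final `assembly_product`, or (if `keep_intermediates`) a
#'   list with `product` and `intermediates`.
#' @export
simulate_plan <- function(plan, toolkit, cargo, keep_intermediates = FALSE) {
  stopifnot(is(plan, "assembly_plan"), is(toolkit, "mobius_toolkit"))
  if (length(cargo) != plan$n_tus)
    stop("need ", plan$n_tus, " TU cargo entries, got ", length(cargo),
         call. = FALSE)
  made <- list()
  for (s in plan$steps) {
    acceptor <- toolkit$vectors[[s$vector]]
    inserts <- list()
    for (ref in s$inputs) {
      if (startsWith(ref, "tu:")) {
        tu <- cargo[[as.integer(sub("tu:", "", ref))]]
        inserts <- c(inserts, list(tu$promoter, tu$cds, tu$terminator))
      } else {
        if (is.null(made[[ref]]))
          stop("step ", s$id, " references unknown product '", ref, "'",
               call. = FALSE)
        inserts <- c(inserts, list(made[[ref]]$molecule))
      }
    }
    if (!is.na(s$linker))
      inserts <- c(inserts, list(toolkit$aux[[s$linker]]))
    enz <- if (s$level == 1L) "BsaI" else "AarI"
    res <- simulate_one_pot(reaction_mix(acceptor, inserts, enz))
    if (res$diagnostics$failure_mode != "none")
      stop("plan failed at step ", s$id, " (", s$vector, ", ", enz, "): ",
           res$diagnostics$failure_mode, " -- ", res$diagnostics$detail,
           call. = FALSE)
    res$product$molecule$id <- sprintf("%s::%s", plan$final, s$id)
    made[[s$id]] <- res$product
  }
  final <- made[[plan$final]]
  final$molecule$id <- sprintf("mobius_%dTU", plan$n_tus)
  if (keep_intermediates) list(product = final, intermediates = made)
  else final
}

#' Ordered payload labels on a molecule
#'
#' Convenience accessor used to check that a multi-TU product carries its
#' payloads in input order: returns the labels of `"payload"`-type
#' features sorted by position.
#'
#' @param m A `dna_molecule` or `assembly_product`.
#' @return Character vector of labels.
#' @export
payload_order <- function(m) {
  if (is(m, "assembly_product")) m <- m$molecule
  f <- m$features[m$features$type == "payload", , drop = FALSE]
  f$label[order(f$start)]
}
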