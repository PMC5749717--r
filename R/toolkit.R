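## Deterministic synthetic Mobius toolkit.
##
## Fixture layouts (top strand, circular; 0-based cut arithmetic):
##
## mUAV        [CmR stub] GAATTC GGTCTCT aaaa GCAGGTG [amilCP] CACCTGC aaaa TGAGACC CTGCAG
##   AarI cuts through the BsaI sequence: the left junction GGTCTCT exposes
##   CTCT (its positions 3-6), the right junction TGAGACC exposes TGAG, and
##   ligating a correctly tailed insert (...CTCT GGAG cargo AATG TGAG...)
##   reconstitutes two inward-facing BsaI sites that later release the part
##   with its standard overhangs.
##
## L1-k        [KanR stub] GAATTC CACCTGC aaaa <out5> CA GGAG A GAGACC [spisPink]
##                 GGTCTC A CGCT CA <out3> aaaa GCAGGTG CTGCAG
##   BsaI acceptance exposes the inner GGAG/CGCT (recognitions sit in the
##   dropout, so its re-ligation stays invalid); AarI release exposes the
##   vector-specific outer overhangs <out5>/<out3> (recognitions stay in
##   the backbone).
##
## L2-k        [CmR stub] GAATTC GGTCTC T <out5> CA GGAG aaaa GCAGGTG [sfGFP]
##                 CACCTGC aaaa ACCC CTGCAG
##   AarI acceptance exposes GGAG/ACCC; the single backbone BsaI site is
##   the 5' half of the later cassette release (the 3' half is donated by
##   the Auxiliary linker).
##
## Aux-x       [KanR stub] GAATTC CACCTGC aaaa [50-bp linker] aaaa GCAGGTG CTGCAG
##   linker =  <up(4)> f1(15) <payload(4)> A GAGACC f2(16) ACCC(4)   (= 50)
##
## L0 part     [CmR stub] GAATTC GGTCTCT <ov5> cargo <ov3> TGAGACC CTGCAG

FORBIDDEN_PATTERNS <- c("CACCTGC", "GCAGGTG", "GGTCTC", "GAGACC",
                        "GAATTC", "CTGCAG")
LINKER_F1 <- "CTTCTTCTTCTTCTT"    # 15 nt, site-free against all junctions
LINKER_F2 <- "CTTCTTCTTCTTCTTC"   # 16 nt

## Evaluate code under a fixed RNG seed without disturbing the caller's
## random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## Random stub free of every Mobius-relevant pattern on both strands
## (Type IIS recognitions plus the EcoRI/PstI demarcation sites, so those
## stay unique per vector).  Rejection sampling; deterministic given the
## RNG state.
site_free_dna <- function(n, max_tries = 1000L) {
  pats <- unique(c(FORBIDDEN_PATTERNS, vapply(FORBIDDEN_PATTERNS, rc, "")))
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    if (!any(vapply(pats, function(p) grepl(p, s, fixed = TRUE), logical(1))))
      return(s)
  }
  stop("failed to sample a site-free stub of length ", n, call. = FALSE)
}

#' Configuration for synthetic toolkit generation
#'
#' Generation is a pure function of this configuration: the same config
#' yields bit-identical sequences.
#'
#' @param seed Integer RNG seed.
#' @param backbone_stub_length Length of the random replication/backbone
#'   stub in every vector (default 2000 nt, a length-realistic stand-in
#'   for an ori plus spacer).
#' @param marker_stub_lengths Named lengths of the chromoprotein marker
#'   stubs (labelled amilCP/spisPink/sfGFP; length-realistic, no coding
#'   claim).
#' @param resistance_stub_lengths Named lengths of the resistance-gene
#'   stubs.
#' @param cargo_length_range Range for random dummy part cargo lengths.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           backbone_stub_length = 2000L,
                           marker_stub_lengths = c(amilCP = 680L,
                                                   spisPink = 690L,
                                                   sfGFP = 710L),
                           resistance_stub_lengths = c(chloramphenicol = 660L,
                                                       kanamycin = 816L),
                           cargo_length_range = c(180L, 600L)) {
  structure(list(seed = as.integer(seed),
                 backbone_stub_length = as.integer(backbone_stub_length),
                 marker_stub_lengths = marker_stub_lengths,
                 resistance_stub_lengths = resistance_stub_lengths,
                 cargo_length_range = as.integer(cargo_length_range)),
            class = "fixture_config")
}

feature_row <- function(label, type, start, end, strand = "+") {
  data.frame(label = label, type = type, start = as.integer(start),
             end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
}

## Assemble a circular plasmid from named blocks; blocks named in
## `annotate` become features (label = block name, type from the map).
build_plasmid <- function(id, blocks, annotate = list()) {
  feats <- list()
  pos <- 0L
  for (nm in names(blocks)) {
    w <- nchar(blocks[[nm]])
    if (nm %in% names(annotate))
      feats[[length(feats) + 1L]] <-
        feature_row(annotate[[nm]]$label, annotate[[nm]]$type, pos, pos + w)
    pos <- pos + w
  }
  dna_molecule(id, paste(unlist(blocks), collapse = ""), "circular",
               if (length(feats)) do.call(rbind, feats) else NULL)
}

expect_site_counts <- function(m, aari, bsai) {
  nrow(find_sites(m, "AarI")) == aari && nrow(find_sites(m, "BsaI")) == bsai
}

## Generate, with bounded retries, a vector whose random stubs do not
## create accidental recognition sites across block junctions.
generate_checked <- function(builder, aari, bsai, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    m <- builder()
    if (expect_site_counts(m, aari, bsai)) return(m)
  }
  stop("could not generate '", m$id, "' without accidental sites", call. = FALSE)
}

backbone_blocks <- function(cfg, resistance) {
  res_len <- cfg$resistance_stub_lengths[[resistance]]
  list(ori_stub = site_free_dna(cfg$backbone_stub_length),
       res = site_free_dna(res_len))
}

build_muav <- function(cfg) {
  generate_checked(function() {
    bb <- backbone_blocks(cfg, "chloramphenicol")
    build_plasmid("mUAV", c(bb, list(
      ecoRI = "GAATTC",
      left_junction = "GGTCTCT",        # AarI exposes CTCT through the BsaI site
      drop_pad_l = "AAAA",
      aarl_l = "GCAGGTG",               # AarI on the bottom strand, cuts left
      marker = site_free_dna(cfg$marker_stub_lengths[["amilCP"]]),
      aarl_r = "CACCTGC",               # AarI on the top strand, cuts right
      drop_pad_r = "AAAA",
      right_junction = "TGAGACC",       # AarI exposes TGAG; GAGACC = BsaI (-)
      pstI = "CTGCAG")),
      annotate = list(res = list(label = "CmR", type = "resistance"),
                      marker = list(label = "amilCP", type = "marker")))
  }, aari = 2L, bsai = 2L)
}

build_l1 <- function(cfg, pos) {
  spec <- vector_spec(paste0("L1-", pos))
  out5 <- spec$outer_overhangs[1]
  out3 <- spec$outer_overhangs[2]
  generate_checked(function() {
    bb <- backbone_blocks(cfg, "kanamycin")
    build_plasmid(spec$name, c(bb, list(
      ecoRI = "GAATTC",
      aarl_out_l = "CACCTGC", pad_l = "AAAA", out5 = out5,
      spacer_l = "CA",
      inner5 = "GGAG", bsa_sp_l = "A", bsal_l = "GAGACC",  # BsaI (-) in dropout
      marker = site_free_dna(cfg$marker_stub_lengths[["spisPink"]]),
      bsal_r = "GGTCTC", bsa_sp_r = "A", inner3 = "CGCT",  # BsaI (+) in dropout
      spacer_r = "CA",
      out3 = out3, pad_r = "AAAA", aarl_out_r = "GCAGGTG",
      pstI = "CTGCAG")),
      annotate = list(res = list(label = "KanR", type = "resistance"),
                      marker = list(label = "spisPink", type = "marker")))
  }, aari = 2L, bsai = 2L)
}

build_l2 <- function(cfg, pos) {
  spec <- vector_spec(paste0("L2-", pos))
  out5 <- spec$outer_overhangs[1]
  generate_checked(function() {
    bb <- backbone_blocks(cfg, "chloramphenicol")
    build_plasmid(spec$name, c(bb, list(
      ecoRI = "GAATTC",
      bsal_out = "GGTCTC", bsa_sp = "T", out5 = out5,   # cassette release, 5' half
      spacer_l = "CA",
      inner5 = "GGAG", pad_l = "AAAA", aarl_l = "GCAGGTG",  # AarI (-) in dropout
      marker = site_free_dna(cfg$marker_stub_lengths[["sfGFP"]]),
      aarl_r = "CACCTGC", pad_r = "AAAA", inner3 = "ACCC",  # AarI (+) in dropout
      pstI = "CTGCAG")),
      annotate = list(res = list(label = "CmR", type = "resistance"),
                      marker = list(label = "sfGFP", type = "marker")))
  }, aari = 2L, bsai = 1L)
}

linker_sequence <- function(name) {
  spec <- linker_spec(name)
  paste0(spec$upstream_overhang, LINKER_F1, spec$payload_overhang,
         "A", "GAGACC", LINKER_F2, spec$downstream_overhang)
}

build_aux <- function(cfg, name) {
  spec <- linker_spec(name)
  link <- linker_sequence(name)
  stopifnot(nchar(link) == spec$length)
  id <- paste0("pAux-", name)
  generate_checked(function() {
    bb <- backbone_blocks(cfg, "kanamycin")
    build_plasmid(id, c(bb, list(
      ecoRI = "GAATTC",
      aarl_l = "CACCTGC", pad_l = "AAAA",
      linker = link,
      pad_r = "AAAA", aarl_r = "GCAGGTG",
      pstI = "CTGCAG")),
      annotate = list(res = list(label = "KanR", type = "resistance"),
                      linker = list(label = paste0("linker_", name),
                                    type = "linker")))
  }, aari = 2L, bsai = 1L)
}

#' Generate the synthetic 16-vector Mobius toolkit
#'
#' Builds the full toolkit -- 1 universal acceptor, 4 Level 1 and 4 Level
#' 2 acceptor vectors, and 7 Auxiliary Plasmids -- as synthetic circular
#' plasmids with the standard's exact recognition-site architecture,
#' overhang routing, dropout markers (length-realistic labelled stubs,
#' not real coding sequences) and resistance features.  Random stub
#' sequences are rejection-sampled free of AarI/BsaI/EcoRI/PstI sites;
#' generation is a pure function of the configuration.
#'
#' @param cfg A [fixture_config()].
#' @return A `mobius_toolkit`: list with `vectors` (named list of the 9
#'   acceptors), `aux` (named list of the 7 Auxiliary Plasmids), `config`
#'   and a `manifest` data frame.
#' @examples
#' tk <- build_toolkit(fixture_config(seed = 1))
#' length(tk$vectors) + length(tk$aux)  # 16
#' @export
build_toolkit <- function(cfg = fixture_config()) {
  stopifnot(is(cfg, "fixture_config"))
  with_seed(cfg$seed, {
    vectors <- list(mUAV = build_muav(cfg))
    for (pos in POSITION_LETTERS)
      vectors[[paste0("L1-", pos)]] <- build_l1(cfg, pos)
    for (pos in POSITION_LETTERS)
      vectors[[paste0("L2-", pos)]] <- build_l2(cfg, pos)
    aux <- setNames(lapply(linker_names(), function(nm) build_aux(cfg, nm)),
                    linker_names())
    manifest <- rbind(
      do.call(rbind, lapply(names(vectors), function(nm) {
        sp <- vector_spec(nm)
        data.frame(name = nm, class = "acceptor", level = sp$level,
                   marker = sp$dropout_marker, resistance = sp$resistance,
                   length = seq_length(vectors[[nm]]),
                   overhangs = paste(stats::na.omit(c(sp$inner_overhangs,
                                                      sp$outer_overhangs)),
                                     collapse = "/"),
                   stringsAsFactors = FALSE)
      })),
      do.call(rbind, lapply(names(aux), function(nm) {
        sp <- linker_spec(nm)
        data.frame(name = paste0("pAux-", nm), class = "auxiliary", level = 2L,
                   marker = "none", resistance = "kanamycin",
                   length = seq_length(aux[[nm]]),
                   overhangs = paste(sp$upstream_overhang, sp$payload_overhang,
                                     sp$downstream_overhang, sep = "/"),
                   stringsAsFactors = FALSE)
      })))
    structure(list(vectors = vectors, aux = aux, config = cfg,
                   manifest = manifest),
              class = "mobius_toolkit")
  })
}

#' @export
print.mobius_toolkit <- function(x, ...) {
  cat(sprintf("<mobius_toolkit> %d acceptor vector(s) + %d Auxiliary Plasmid(s), seed %d\n",
              length(x$vectors), length(x$aux), x$config$seed))
  print(x$manifest)
  invisible(x)
}

## A Level 0 storage plasmid holding ov5+cargo+ov3 behind the
## mUAV-derived junctions (shape identical to a real mUAV reaction
## product; see build_level0() for the simulated route).
level0_plasmid <- function(cfg, id, cargo, ov5, ov3, cargo_features = NULL) {
  for (try in 1:50) {
    bb <- backbone_blocks(cfg, "chloramphenicol")
    blocks <- c(bb, list(
      ecoRI = "GAATTC",
      left_junction = "GGTCTCT",
      part = paste0(ov5, cargo, ov3),
      right_junction = "TGAGACC",
      pstI = "CTGCAG"))
    m <- build_plasmid(id, blocks,
                       annotate = list(res = list(label = "CmR", type = "resistance")))
    if (expect_site_counts(m, aari = 0L, bsai = 2L)) break
    if (try == 50L)
      stop("could not generate '", id, "' without accidental sites", call. = FALSE)
  }
  if (!is.null(cargo_features)) {
    off <- sum(nchar(unlist(blocks[c("ori_stub", "res", "ecoRI", "left_junction")]))) +
      nchar(ov5)
    cargo_features$start <- cargo_features$start + off
    cargo_features$end <- cargo_features$end + off
    m$features <- rbind(m$features, cargo_features)
    m$features <- m$features[order(m$features$start), , drop = FALSE]
    rownames(m$features) <- NULL
  }
  m
}

## Sample cargo whose TU chain (with every possible vector flank) stays
## free of forbidden sites, so junction-spanning sites cannot arise later.
sample_tu_cargo <- function(cfg, overhang_table, max_tries = 200L) {
  lens <- function() sample(cfg$cargo_length_range[1]:cfg$cargo_length_range[2], 1L)
  outs <- c("GGAG", "CAGA", "GTCA", "CTTG", "CGCT")
  pats <- c("CACCTGC", "GCAGGTG", "GGTCTC", "GAGACC")
  for (i in seq_len(max_tries)) {
    prom <- site_free_dna(lens())
    cds <- site_free_dna(lens())
    term <- site_free_dna(lens())
    chain <- paste0("GGAG", prom, "AATG", cds, "GCTT", term, "CGCT")
    ok <- TRUE
    for (o5 in outs) for (o3 in outs) {
      ctx <- paste0(o5, "CA", chain, "CA", o3)
      if (any(vapply(pats, function(p)
        grepl(p, ctx, fixed = TRUE) || grepl(rc(p), ctx, fixed = TRUE),
        logical(1)))) { ok <- FALSE; break }
    }
    if (ok) return(list(promoter = prom, cds = cds, terminator = term))
  }
  stop("failed to sample site-free TU cargo", call. = FALSE)
}

#' Generate dummy Level 0 part plasmids for n transcriptional units
#'
#' For each TU, three Level 0 storage plasmids (promoter, CDS,
#' terminator) with random forbidden-site-free cargo and the standard
#' part overhangs; every CDS cargo carries a unique `payload` feature
#' label (`payload_01`, ...) so the order of TUs can be tracked through
#' any assembly.  Deterministic given the configuration seed (offset so
#' the parts differ from the toolkit stubs).
#'
#' @param cfg A [fixture_config()].
#' @param n Number of TUs (>= 1).
#' @return List of `n` lists with elements `promoter`, `cds`,
#'   `terminator` (each a circular `dna_molecule`).
#' @export
build_dummy_tu_parts <- function(cfg = fixture_config(), n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  tbl <- DEFAULT_PART_OVERHANGS
  with_seed(cfg$seed + 104729L, {   # distinct stream from build_toolkit()
    lapply(seq_len(n), function(i) {
      cargo <- sample_tu_cargo(cfg, tbl)
      tag <- sprintf("%02d", i)
      list(
        promoter = level0_plasmid(cfg, paste0("L0-prom-", tag), cargo$promoter,
                                  "GGAG", "AATG",
                                  feature_row(paste0("prom_", tag), "part",
                                              0L, nchar(cargo$promoter))),
        cds = level0_plasmid(cfg, paste0("L0-cds-", tag), cargo$cds,
                             "AATG", "GCTT",
                             feature_row(paste0("payload_", tag), "payload",
                                         0L, nchar(cargo$cds))),
        terminator = level0_plasmid(cfg, paste0("L0-term-", tag), cargo$terminator,
                                    "GCTT", "CGCT",
                                    feature_row(paste0("term_", tag), "part",
                                                0L, nchar(cargo$terminator))))
    })
  })
}

#' Export a toolkit as GenBank files plus a manifest
#'
#' Writes one GenBank file per vector and a YAML manifest (name, class,
#' level, marker, resistance, length, overhangs) into `dir`.
#'
#' @param toolkit A `mobius_toolkit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_toolkit <- function(toolkit, dir) {
  stopifnot(is(toolkit, "mobius_toolkit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in c(toolkit$vectors, toolkit$aux))
    write_genbank(m, file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", m$id), ".gb")))
  yaml::write_yaml(lapply(seq_len(nrow(toolkit$manifest)), function(i)
    as.list(toolkit$manifest[i, ])), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
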