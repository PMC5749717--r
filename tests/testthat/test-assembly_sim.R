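## Reactions run on the shared fixture toolkit `tk` (helper-fixtures.R).

make_amplicon <- function(cargo, ov5 = "AATG", ov3 = "GCTT", id = "amp") {
  tpl <- dna_molecule(id, cargo, "linear",
                      data.frame(label = paste0(id, "_payload"), type = "payload",
                                 start = 0L, end = nchar(cargo), strand = "+"))
  design <- design_primers(tpl, overhangs = c(ov5, ov3))
  pcr_amplicon(design, tpl)
}

test_that("the mUAV reaction swaps the amilCP dropout for the new part", {
  amp <- make_amplicon(clean_cargo(200))
  res <- simulate_one_pot(reaction_mix(tk$vectors$mUAV, list(amp), "AarI"))
  expect_equal(res$diagnostics$failure_mode, "none")
  p <- res$product
  expect_true(p$valid)
  expect_false("amilCP" %in% p$molecule$features$label)
  expect_true("amp_payload" %in% p$molecule$features$label)
  expect_equal(nrow(find_sites(p$molecule, "AarI")), 0L)
  ## inward-facing BsaI sites are reconstituted at the fusion junctions
  expect_equal(nrow(find_sites(p$molecule, "BsaI")), 2L)
})

test_that("an acceptor alone yields no closed cycle (dropout re-ligation invalid)", {
  res <- simulate_one_pot(reaction_mix(tk$vectors$`L1-A`, list(), "BsaI"))
  expect_null(res$product)
  expect_equal(res$diagnostics$failure_mode, "no_closed_cycle")
})

test_that("an acceptor without sites for the reaction enzyme reports uncut_input", {
  dead <- dna_molecule("dead", clean_cargo(300), "circular",
                       data.frame(label = "CmR", type = "resistance",
                                  start = 10L, end = 200L, strand = "+"))
  res <- simulate_one_pot(reaction_mix(dead, list(), "AarI"))
  expect_equal(res$diagnostics$failure_mode, "uncut_input")
})

test_that("a duplicated overhang among junctions is reported as overhang_clash", {
  amp1 <- make_amplicon(clean_cargo(150), id = "a1")
  amp2 <- make_amplicon(clean_cargo(160), id = "a2")  # same CTCT/TGAG ends
  res <- simulate_one_pot(reaction_mix(tk$vectors$mUAV, list(amp1, amp2), "AarI"))
  expect_null(res$product)
  expect_equal(res$diagnostics$failure_mode, "overhang_clash")
})

test_that("a Level 2 reaction fuses four TUs plus the 4A linker uniquely", {
  cargo <- tu_cargo16[1:4]
  l1 <- lapply(1:4, function(i) {
    vec <- paste0("L1-", c("A", "B", "G", "D")[i])
    res <- simulate_one_pot(reaction_mix(
      tk$vectors[[vec]],
      list(cargo[[i]]$promoter, cargo[[i]]$cds, cargo[[i]]$terminator), "BsaI"))
    expect_equal(res$diagnostics$failure_mode, "none")
    res$product
  })
  res <- simulate_one_pot(reaction_mix(
    tk$vectors$`L2-A`,
    c(lapply(l1, function(p) p$molecule), list(tk$aux$`4A`)), "AarI"))
  expect_equal(res$diagnostics$failure_mode, "none")
  p <- res$product
  expect_equal(payload_order(p), sprintf("payload_%02d", 1:4))
  expect_true("linker_4A" %in% p$molecule$features$label)
  expect_equal(nrow(find_sites(p$molecule, "AarI")), 0L)
  ## exactly the two cassette-release BsaI sites remain
  expect_equal(nrow(find_sites(p$molecule, "BsaI")), 2L)

  ## cassette release: outer 5' of L2-A and the 4A payload overhang
  cas <- cassette_of(p, "BsaI")
  expect_equal(cas$left_overhang, "GGAG")
  expect_equal(cas$right_overhang, "CAGA")
})

test_that("cassette_of releases Level 1 cassettes with the routed outer overhangs", {
  cargo <- tu_cargo16[[1]]
  for (pos in c("A", "B", "G", "D")) {
    vec <- paste0("L1-", pos)
    res <- simulate_one_pot(reaction_mix(
      tk$vectors[[vec]],
      list(cargo$promoter, cargo$cds, cargo$terminator), "BsaI"))
    expect_equal(res$diagnostics$failure_mode, "none")
    cas <- cassette_of(res$product, "AarI")
    expect_equal(c(cas$left_overhang, cas$right_overhang),
                 vector_spec(vec)$outer_overhangs, info = vec)
    expect_equal(unname(cas$carries_sites["AarI"]), 0L)
  }
})

test_that("cassette_of demands exactly two release cuts", {
  expect_error(cassette_of(tk$vectors$mUAV, "AarI"), NA)  # 2 cuts: fine
  expect_error(cassette_of(dna_molecule("x", clean_cargo(100), "circular",
                                        data.frame(label = "CmR", type = "resistance",
                                                   start = 0L, end = 50L,
                                                   strand = "+")),
                           "BsaI"),
               "release error")
})

test_that("simulate_plan preserves payload order and conserves length", {
  plan <- plan_assembly(4)
  res <- simulate_plan(plan, tk, tu_cargo16[1:4], keep_intermediates = TRUE)
  final <- res$product
  expect_equal(payload_order(final), sprintf("payload_%02d", 1:4))
  expect_true("linker_4D" %in% final$molecule$features$label)

  ## conservation: final length = L2 backbone contribution + cassette
  ## contributions, junction 4-mers counted once
  bb <- digest(tk$vectors$`L2-A`, "AarI")
  bb <- bb[[which(vapply(bb, function(f)
    any(f$features$type == "resistance"), logical(1)))]]
  cassettes <- lapply(res$intermediates[sprintf("s%02d", 1:4)], function(p)
    cassette_of(p, "AarI"))
  linker <- digest(tk$aux$`4D`, "AarI")
  linker <- linker[[which(vapply(linker, function(f)
    !any(f$features$type == "resistance"), logical(1)))]]
  pieces <- c(list(bb), cassettes, list(linker))
  expected_len <- sum(vapply(pieces, function(f) nchar(f$core) - 4L, integer(1)))
  expect_equal(seq_length(final$molecule), expected_len)
})

test_that("every product is free of its reaction enzyme's sites (n = 2, 3)", {
  for (n in 2:3) {
    plan <- plan_assembly(n)
    res <- simulate_plan(plan, tk, tu_cargo16[seq_len(n)], keep_intermediates = TRUE)
    for (sid in names(res$intermediates)) {
      step <- plan$steps[[sid]]
      enz <- if (step$level == 1L) "BsaI" else "AarI"
      expect_equal(nrow(find_sites(res$intermediates[[sid]]$molecule, enz)), 0L,
                   info = paste(n, sid))
    }
  }
})

test_that("product GenBank export round-trips", {
  res <- simulate_plan(plan_assembly(1), tk, tu_cargo16[1])
  path <- tempfile(fileext = ".gb")
  write_genbank(res$molecule, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, res$molecule$sequence)
  expect_equal(back$topology, "circular")
  expect_setequal(back$features$label, res$molecule$features$label)
  unlink(path)
})
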