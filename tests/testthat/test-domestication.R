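test_that("scan_sites merges hits across enzymes and strands", {
  m <- dna_molecule("x", paste0(strrep("AT", 10), "CACCTGC", strrep("TA", 10)))
  rep <- scan_sites(m)
  expect_true(rep$needs_domestication)
  expect_equal(nrow(rep$hits), 1L)
  expect_equal(rep$hits$enzyme, "AarI")

  ## BsaI on the bottom strand only
  m2 <- dna_molecule("y", paste0(strrep("AT", 10), "GAGACC", strrep("TA", 10)))
  rep2 <- scan_sites(m2)
  expect_equal(rep2$hits$enzyme, "BsaI")
  expect_equal(rep2$hits$strand, "-")

  expect_false(scan_sites(dna_molecule("z", strrep("AT", 30)))$needs_domestication)
})

test_that("Monte-Carlo site counts match the closed-form density", {
  set.seed(23)
  n_seq <- 1000L
  len <- 1000L
  counts <- vapply(seq_len(n_seq), function(i)
    nrow(scan_sites(dna_molecule("r", random_seq(len)))$hits), integer(1))
  expected <- len * site_density(c(7, 6))   # AarI + BsaI, both strands
  se <- stats::sd(counts) / sqrt(n_seq)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("burden_reduction reproduces the analytic reductions", {
  expect_equal(round(burden_reduction(c(6, 7), c(6, 6, 6)), 1), 58.3)
  expect_equal(burden_reduction(c(6, 7), c(6, 6)), 37.5)
  expect_equal(burden_reduction(c(6, 7), c(6, 7)), 0)
  ## strand-factor invariance: one- vs both-strand densities give the
  ## same ratio, and the GC-weighted model at 50% GC agrees with lengths
  expect_equal(site_density(c(6, 7)) / site_density(c(6, 6, 6)),
               site_density(c(6, 7), both_strands = FALSE) /
                 site_density(c(6, 6, 6), both_strands = FALSE))
  expect_equal(site_density(c("GGTCTC", "CACCTGC"), gc = 0.5),
               site_density(c(6, 7)))
  expect_error(burden_reduction(numeric(), c(6)), "non-empty")
})

test_that("domesticate_cds removes a spanning site with one synonymous edit", {
  m <- dna_molecule("cds", "ATGGGTCTCTAA")
  res <- domesticate_cds(m)
  expect_length(res$edits, 1L)
  expect_false(scan_sites(res$molecule)$needs_domestication)
  expect_equal(translate_cds(res$molecule$sequence), translate_cds(m$sequence))

  ## minimality oracle: no zero-edit solution exists (the site is there),
  ## and exhaustive search confirms at least one single-codon fix
  expect_true(scan_sites(m)$needs_domestication)
  syn <- mobius:::codon_table()
  gc <- Biostrings::GENETIC_CODE
  fixes <- 0L
  for (ci in 0:3) {
    orig <- substr(m$sequence, 3 * ci + 1, 3 * ci + 3)
    for (alt in setdiff(syn[[unname(gc[orig])]], orig)) {
      cand <- paste0(substr(m$sequence, 1, 3 * ci), alt,
                     substr(m$sequence, 3 * ci + 4, 12))
      if (!scan_sites(dna_molecule("c", cand))$needs_domestication)
        fixes <- fixes + 1L
    }
  }
  expect_gt(fixes, 0L)
})

test_that("domestication is a no-op on clean sequences and deterministic", {
  m <- dna_molecule("cds", "ATGAAAGAAGATTAA")
  expect_length(domesticate_cds(m)$edits, 0L)

  expect_error(domesticate_cds(dna_molecule("cds", "ATGGGTCTCTA")),
               "divisible")  # frame guard

  two <- dna_molecule("cds", "ATGGGTCTCTATCACCTGCATTAA")
  r1 <- domesticate_cds(two)
  r2 <- domesticate_cds(two)
  expect_identical(r1$molecule$sequence, r2$molecule$sequence)
  expect_length(r1$edits, 2L)
  expect_false(scan_sites(r1$molecule)$needs_domestication)
  expect_equal(translate_cds(r1$molecule$sequence), translate_cds(two$sequence))
})

test_that("domestication preserves translation on random mutagenized CDSs", {
  set.seed(29)
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  syn <- mobius:::codon_table()
  for (i in 1:50) {
    n_codons <- sample(30:80, 1)
    body <- paste(vapply(sample(aas, n_codons, replace = TRUE),
                         function(a) sample(syn[[a]], 1), ""), collapse = "")
    seq <- paste0("ATG", body, "TAA")
    ## inject a forbidden site at a random codon boundary
    at <- 3 * sample(2:(n_codons - 3), 1)
    site <- sample(c("GGTCTC", "GAGACC", "CACCTGC", "GCAGGTG"), 1)
    pad <- if (nchar(site) == 7) "AT" else ""
    seq <- paste0(substr(seq, 1, at), site, pad,
                  substr(seq, at + nchar(site) + nchar(pad) + 1, nchar(seq)))
    seq <- substr(seq, 1, 3 * (nchar(seq) %/% 3))
    m <- dna_molecule("mut", seq)
    res <- tryCatch(domesticate_cds(m), error = function(e) e)
    if (inherits(res, "error")) {
      expect_match(conditionMessage(res), "unresolvable")
    } else {
      expect_false(scan_sites(res$molecule)$needs_domestication)
      expect_equal(translate_cds(res$molecule$sequence),
                   translate_cds(m$sequence))
    }
  }
})

test_that("unbreakable sites raise an unresolvable-site error", {
  ## a custom forbidden motif made entirely of single-codon amino acids
  ## (Met-Trp) cannot be broken synonymously
  metTrp <- type_iis_enzyme("MetTrp", "ATGTGG", 1L, 4L)
  m <- dna_molecule("cds", "ATGTGGAAATAA")
  expect_error(domesticate_cds(m, forbidden = list(metTrp)), "unresolvable")
})

test_that("site reports export as TSV", {
  m <- dna_molecule("x", paste0(strrep("AT", 5), "CACCTGC", strrep("TA", 5)))
  path <- tempfile(fileext = ".tsv")
  write_site_report(scan_sites(m), path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$enzyme, "AarI")
  unlink(path)
})
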