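test_that("reverse_complement pairs bases and is an involution", {
  expect_equal(reverse_complement(dna_molecule("x", "ACGT"))$sequence, "ACGT")
  expect_equal(reverse_complement(dna_molecule("x", "CACCTGC"))$sequence,
               "GCAGGTG")
  for (s in 0:99) {
    set.seed(s)
    m <- dna_molecule("r", random_seq(200), "linear")
    expect_identical(reverse_complement(reverse_complement(m))$sequence,
                     m$sequence)
  }
  ## features mirror and flip strand
  m <- dna_molecule("f", "AAAACGTTTT", "linear",
                    data.frame(label = "x", type = "part", start = 1L,
                               end = 4L, strand = "+"))
  r <- reverse_complement(m)
  expect_equal(r$features$start, 6L)
  expect_equal(r$features$end, 9L)
  expect_equal(r$features$strand, "-")
})

test_that("degenerate or empty sequences are rejected", {
  expect_error(dna_molecule("x", "ACGN"), "alphabet")
  expect_error(dna_molecule("x", ""), "non-empty")
})

test_that("find_sites locates recognition sites on both strands", {
  aarI <- mobius_enzymes()$AarI
  h <- find_sites(dna_molecule("x", "AAACACCTGCAAA"), aarI)
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 3L)
  expect_equal(h$strand, "+")
  expect_equal(h$cut_top, 3L + 7L + 4L)
  expect_equal(h$cut_bottom, h$cut_top + 4L)

  h2 <- find_sites(dna_molecule("x", "AAAGCAGGTGAAA"), aarI)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$position, 3L)
})

test_that("find_sites agrees with the naive oracle on random circular molecules", {
  set.seed(7)
  enzymes <- mobius_enzymes()
  for (i in 1:100) {
    m <- dna_molecule("r", random_seq(300), "circular")
    for (e in enzymes)
      expect_equal(nrow(find_sites(m, e)),
                   naive_site_count(m$sequence, TRUE, e$recognition),
                   info = sprintf("iter %d enzyme %s", i, e$name))
  }
})

test_that("strand symmetry: counts match on the reverse complement with mirrored strands", {
  set.seed(11)
  for (i in 1:25) {
    m <- dna_molecule("r", random_seq(400), "circular")
    h1 <- find_sites(m, "BsaI")
    h2 <- find_sites(reverse_complement(m), "BsaI")
    expect_equal(nrow(h1), nrow(h2))
    expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
  }
})

test_that("digest releases cargo with the expected sticky overhangs", {
  cargo <- clean_cargo(40)
  m <- two_site_circle(cargo, "GGAG", "CGCT")
  frags <- digest(m, "BsaI")
  expect_length(frags, 2L)
  cargo_frag <- frags[[which(vapply(frags, function(f)
    grepl(cargo, f$core, fixed = TRUE), logical(1)))]]
  expect_equal(cargo_frag$left_overhang, "GGAG")
  expect_equal(cargo_frag$right_overhang, "CGCT")
  expect_equal(cargo_frag$core, paste0("GGAG", cargo, "CGCT"))
  expect_equal(unname(cargo_frag$carries_sites["BsaI"]), 0L)
  backbone <- frags[[which(vapply(frags, function(f)
    !grepl(cargo, f$core, fixed = TRUE), logical(1)))]]
  expect_equal(unname(backbone$carries_sites["BsaI"]), 2L)
})

test_that("digest handles blunt, uncut and off-end cases", {
  lin <- dna_molecule("x", "ACGTACGTACGT", "linear")
  frags <- digest(lin, "BsaI")
  expect_length(frags, 1L)
  expect_equal(frags[[1]]$left_overhang, "")
  expect_equal(frags[[1]]$right_overhang, "")
  expect_false(frags[[1]]$uncut)

  circ <- dna_molecule("x", "ACGTACGTACGT", "circular")
  frags <- digest(circ, "BsaI")
  expect_true(frags[[1]]$uncut)

  ## cut arithmetic runs off the right end of a linear molecule
  expect_error(digest(dna_molecule("x", "AAGGTCTCTGG", "linear"), "BsaI"),
               "geometry")
})

test_that("length conservation holds for random two-site circles", {
  set.seed(13)
  for (i in 1:200) {
    m <- two_site_circle(clean_cargo(sample(20:120, 1)))
    frags <- digest(m, "BsaI")
    expect_equal(sum(vapply(frags, function(f) nchar(f$core) - 4L, integer(1))),
                 seq_length(m))
  }
})

test_that("digestion of a circular molecule is rotation invariant", {
  set.seed(17)
  m <- two_site_circle(clean_cargo(60))
  ref <- sort(vapply(digest(m, "BsaI"), function(f) f$core, ""))
  for (off in c(1, 5, 50, seq_length(m) - 3)) {
    rot <- dna_molecule("rot",
                        paste0(substr(m$sequence, off + 1, seq_length(m)),
                               substr(m$sequence, 1, off)),
                        "circular")
    expect_equal(sort(vapply(digest(rot, "BsaI"), function(f) f$core, "")), ref)
  }
})

test_that("linear digestion yields k+1 fragments and circular k", {
  cargo <- clean_cargo(30)
  seqs <- paste0("GGTCTCT", "GGAG", cargo, "CGCT", "AGAGACC", strrep("CT", 20))
  expect_length(digest(dna_molecule("l", seqs, "linear"), "BsaI"), 3L)
  expect_length(digest(dna_molecule("c", seqs, "circular"), "BsaI"), 2L)
})
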