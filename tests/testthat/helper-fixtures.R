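## Shared fixtures and independent oracles. The toolkit and a 16-TU cargo
## set are built once per test run; build_dummy_tu_parts() is
## prefix-stable in n, so subsets serve the smaller plans.

TK_SEED <- 42L
tk_cfg <- fixture_config(seed = TK_SEED)
tk <- build_toolkit(tk_cfg)
tu_cargo16 <- build_dummy_tu_parts(tk_cfg, 16)

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

## Independent site-finding oracle: naive per-position scan over every
## rotation-relevant position, both strands, circular handled by the
## doubled-and-truncated linearisation.
naive_site_count <- function(seq, circular, recognition) {
  len <- nchar(seq)
  lr <- nchar(recognition)
  subject <- if (circular) paste0(seq, substr(seq, 1, lr - 1)) else seq
  n <- 0L
  limit <- if (circular) len else len - lr + 1L
  if (limit < 1L) return(0L)
  for (p in seq_len(limit)) {
    w <- substr(subject, p, p + lr - 1L)
    if (nchar(w) < lr) next
    if (w == recognition) n <- n + 1L
    if (w == rc_chr(recognition)) n <- n + 1L
  }
  n
}

## A circular test construct with exactly two inward-facing BsaI sites
## releasing cargo with the given overhangs.
two_site_circle <- function(cargo, ov5 = "GGAG", ov3 = "CGCT",
                            filler = strrep("CT", 30)) {
  dna_molecule("two_site",
               paste0("GGTCTCT", ov5, cargo, ov3, "AGAGACC", filler),
               "circular")
}

## Cargo free of AarI/BsaI (and their complements) for construct tests.
clean_cargo <- function(n) {
  repeat {
    s <- random_seq(n)
    m <- dna_molecule("c", s, "linear")
    if (!scan_sites(m)$needs_domestication) return(s)
  }
}
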