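## helpers to interrogate plans
l2_steps <- function(plan) unname(Filter(function(s) s$level == 2L, plan$steps))
linkers_used <- function(plan) unname(unlist(lapply(l2_steps(plan),
                                                    function(s) s$linker)))
tu_steps <- function(plan) Filter(function(s) any(startsWith(s$inputs, "tu:")),
                                  plan$steps)

test_that("capacity follows the geometric law 1, 4, 16, 64", {
  expect_equal(capacity(1), 1L)
  expect_equal(capacity(2), 4L)
  expect_equal(capacity(3), 16L)
  expect_equal(capacity(4), 64L)
  expect_equal(capacity(5), 256L)
  expect_error(capacity(0), "tier")
})

test_that("plan(7) reproduces the worked 4+3 routing", {
  p <- plan_assembly(7)
  l2 <- l2_steps(p)
  expect_length(l2, 2L)
  expect_equal(l2[[1]]$vector, "L2-A")
  expect_equal(l2[[1]]$linker, "4A")
  expect_length(l2[[1]]$inputs, 4L)
  expect_equal(l2[[2]]$vector, "L2-B")
  expect_equal(l2[[2]]$linker, "M3")
  expect_length(l2[[2]]$inputs, 3L)
  final <- p$steps[[p$final]]
  expect_equal(final$level, 1L)
  expect_equal(final$vector, "L1-A")
})

test_that("terminal full chunks take the 4D linker (8- and 12-TU routes)", {
  p8 <- plan_assembly(8)
  expect_equal(vapply(l2_steps(p8), function(s) s$vector, ""),
               c("L2-A", "L2-B"))
  expect_equal(linkers_used(p8), c("4A", "4D"))

  p12 <- plan_assembly(12)
  expect_equal(vapply(l2_steps(p12), function(s) s$vector, ""),
               c("L2-A", "L2-B", "L2-G"))
  expect_equal(linkers_used(p12), c("4A", "4B", "4D"))
})

test_that("plan(5) reproduces the 4+1 route", {
  p <- plan_assembly(5)
  l2 <- l2_steps(p)
  expect_equal(vapply(l2, function(s) s$linker, ""), c("4A", "M1"))
  expect_equal(vapply(l2, function(s) s$vector, ""), c("L2-A", "L2-B"))
  expect_equal(p$steps[[p$final]]$vector, "L1-A")
})

test_that("plan(16) fuses four full Level 2 chunks in L1-A", {
  p <- plan_assembly(16)
  expect_equal(linkers_used(p), c("4A", "4B", "4G", "4D"))
  final <- p$steps[[p$final]]
  expect_equal(final$level, 1L)
  expect_equal(final$vector, "L1-A")
  expect_length(final$inputs, 4L)
})

test_that("degenerate and boundary plans", {
  p1 <- plan_assembly(1)
  expect_length(p1$steps, 1L)
  expect_equal(p1$steps[[1]]$level, 1L)
  expect_equal(p1$rounds, 1L)

  p4 <- plan_assembly(4)
  expect_equal(p4$steps[[p4$final]]$level, 2L)  # single-chunk plans end at Level 2
  expect_equal(linkers_used(p4), "4D")

  expect_error(plan_assembly(0), "n must be")
})

test_that("round counts follow ceil(log4 n) + 1", {
  for (n in 2:20) {
    p <- plan_assembly(n)
    expect_equal(p$rounds, ceiling(log(n, 4)) + 1L, info = paste("n =", n))
  }
  expect_equal(plan_assembly(64)$rounds, 4L)
  ## the post-TU-construction reaction count for 64 TUs: 16 L2 + 4 L1 + 1 L2
  p64 <- plan_assembly(64)
  expect_equal(sum(vapply(p64$steps, function(s) s$round > 1L, logical(1))), 21L)
})

test_that("chunking is left-packed with at most four TUs per Level 2 reaction", {
  for (n in 1:32) {
    p <- plan_assembly(n)
    sizes <- vapply(l2_steps(p), function(s) length(s$inputs), integer(1))
    expect_true(all(sizes <= 4L))
    ## Level 1 steps never carry a linker, Level 2 steps always do
    expect_true(all(vapply(p$steps, function(s)
      is.na(s$linker) == (s$level == 1L), logical(1))))
  }
})

test_that("across plans for n = 1..16 exactly the seven standard linkers appear", {
  used <- unique(unlist(lapply(1:16, function(n) linkers_used(plan_assembly(n)))))
  expect_setequal(used, linker_names())
})

test_that("extend_plan reuses the final cassette and appends new TUs", {
  expect_identical(extend_plan(plan_assembly(1), 0), plan_assembly(1))

  p <- extend_plan(plan_assembly(4), 1)
  expect_equal(p$n_tus, 5L)
  added <- unname(p$steps[(length(plan_assembly(4)$steps) + 1L):length(p$steps)])
  levels <- vapply(added, function(s) s$level, integer(1))
  ## one L1 fusion of the existing product, one L1 TU build, one new L2 step
  expect_equal(sort(levels), c(1L, 1L, 2L))
  l2_new <- added[[which(levels == 2L)]]
  expect_equal(l2_new$linker, "M2")
  expect_equal(l2_new$vector, "L2-A")
  expect_length(l2_new$inputs, 2L)

  expect_error(extend_plan(structure(list(terminal = FALSE),
                                     class = "assembly_plan"), 1),
               "terminal")
})

test_that("plans round-trip through YAML", {
  p <- plan_assembly(7)
  path <- tempfile(fileext = ".yaml")
  write_plan(p, path)
  q <- read_plan(path)
  expect_equal(q$n_tus, p$n_tus)
  expect_equal(names(q$steps), names(p$steps))
  expect_equal(q$steps[["s09"]]$linker, p$steps[["s09"]]$linker)
  expect_equal(q$steps[[q$final]]$inputs, p$steps[[p$final]]$inputs)
  unlink(path)
})

test_that("bench sheets list vectors, linkers and failure colours", {
  sheet <- bench_sheet(plan_assembly(7))
  expect_true(any(grepl("Auxiliary Plasmid 4A", sheet)))
  expect_true(any(grepl("Auxiliary Plasmid M3", sheet)))
  expect_true(any(grepl("magenta", sheet)))
  expect_true(any(grepl("yellow", sheet)))
})
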