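make_profiles <- function(values_by_var, cell_line = "L1") {
  # values_by_var: named list "organelle.analyte" -> numeric per cell
  n <- length(values_by_var[[1]])
  rows <- list()
  for (v in names(values_by_var)) {
    parts <- strsplit(v, ".", fixed = TRUE)[[1]]
    rows[[v]] <- data.frame(cell_line = cell_line,
                            cell_id = sprintf("cell_%03d", seq_len(n)),
                            organelle = parts[1], organelle_index = 1L,
                            analyte = parts[2],
                            concentration_mgml = values_by_var[[v]],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("profile summaries are exact arithmetic per group", {
  one <- make_profiles(list(nucleolus.protein = 85))
  s1 <- summarize_profiles(one)
  expect_equal(s1$n, 1L)
  expect_equal(s1$mean, 85)
  expect_equal(s1$sd, 0)
  expect_equal(s1$min, 85)
  expect_equal(s1$max, 85)

  two_lines <- rbind(make_profiles(list(ER.protein = c(1, 2, 3)), "A"),
                     make_profiles(list(ER.protein = c(10, 20, 30)), "B"))
  s2 <- summarize_profiles(two_lines)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$mean[s2$cell_line == "A"], 2)
  expect_equal(s2$mean[s2$cell_line == "B"], 20)
  expect_equal(s2$sd[s2$cell_line == "B"], 10)
  expect_error(summarize_profiles(two_lines[0, ]), "empty")
})

test_that("group means of a large simulated population recover the generator means", {
  spec <- default_population_spec("WI38", n_cells = 500, seed = 1234)
  pop <- simulate_population(spec)
  s <- summarize_profiles(pop)
  for (i in seq_len(nrow(s))) {
    v <- paste(s$organelle[i], s$analyte[i], sep = ".")
    sem <- spec$sds[[v]] / sqrt(s$n[i])
    expect_lt(abs(s$mean[i] - spec$means[[v]]), 2 * sem + 0.15)
  }
})

test_that("perfect linear dependence gives r of exactly +1 or -1", {
  x <- seq(2, 20, by = 2)
  prof <- make_profiles(list(nucleolus.protein = x, nucleolus.RNA = 2 * x,
                             nucleolus.lipid = -x + 50))
  up <- correlate_within(prof, "nucleolus", c("protein", "RNA"))
  dn <- correlate_within(prof, "nucleolus", c("protein", "lipid"))
  expect_equal(up$r, 1)
  expect_equal(dn$r, -1)
  expect_equal(up$n, 10L)
  expect_equal(up$strength, "strong")
})

test_that("degenerate correlation inputs are errors", {
  prof <- make_profiles(list(nucleolus.protein = c(1, 2, 3),
                             nucleolus.RNA = c(5, 5, 5)))
  expect_error(correlate_within(prof, "nucleolus", c("protein", "RNA")),
               "zero variance")
  tiny <- make_profiles(list(nucleolus.protein = c(1, 2),
                             nucleolus.RNA = c(3, 4)))
  # constructor of the table allows it; the correlation refuses n < 3
  expect_error(correlate_within(tiny, "nucleolus", c("protein", "RNA")),
               "3")
})

test_that("cross-organelle pairing is by cell and honours missing cells", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  prof <- make_profiles(list(nucleolus.protein = x, ER.protein = x))
  same <- correlate_between(prof, "nucleolus", "protein", "ER", "protein")
  expect_equal(same$r, 1)
  # a cell without the second organelle is dropped pairwise
  prof2 <- prof[!(prof$organelle == "ER" & prof$cell_id == "cell_001"), ]
  r2 <- correlate_between(prof2, "nucleolus", "protein", "ER", "protein")
  expect_equal(r2$n, 9L)
  # shuffled row order must not matter: pairing is strictly by cell_id
  prof3 <- prof[sample(nrow(prof)), ]
  expect_equal(correlate_between(prof3, "nucleolus", "protein",
                                 "ER", "protein")$r, 1)
})

test_that("uncorrelated organelles show |r| below the sampling bound", {
  vn <- c("nucleolus.protein", "ER.protein")
  spec <- population_spec(200, "L",
                          means = c(nucleolus.protein = 85, ER.protein = 70),
                          sds = c(nucleolus.protein = 17.5, ER.protein = 25),
                          seed = 777)
  pop <- simulate_population(spec)
  r <- correlate_between(pop, "nucleolus", "protein", "ER", "protein")$r
  expect_lt(abs(r), 0.15)
})

test_that("a 0.75 nucleolus-ER protein coupling is recovered at n = 150", {
  vn <- c("nucleolus.protein", "ER.protein")
  R <- matrix(c(1, 0.75, 0.75, 1), 2, dimnames = list(vn, vn))
  spec <- population_spec(150, "L",
                          means = c(nucleolus.protein = 85, ER.protein = 70),
                          sds = c(nucleolus.protein = 17.5, ER.protein = 25),
                          correlation = R, seed = 1618)
  pop <- simulate_population(spec)
  r <- correlate_between(pop, "nucleolus", "protein", "ER", "protein")$r
  z <- atanh(0.75); hw <- qnorm(0.995) / sqrt(150 - 3)
  expect_gt(r, tanh(z - hw))
  expect_lt(r, tanh(z + hw))
})

test_that("duplicated organelles pair by acquisition order", {
  n <- 20
  set.seed(31)
  m1 <- rnorm(n, 70, 10)
  m2 <- m1 + rnorm(n, 0, 3)      # second mitochondrion tracks the first
  prof <- rbind(
    data.frame(cell_line = "L", cell_id = sprintf("cell_%03d", 1:n),
               organelle = "mitochondrion", organelle_index = 1L,
               analyte = "protein", concentration_mgml = m1),
    data.frame(cell_line = "L", cell_id = sprintf("cell_%03d", 1:n),
               organelle = "mitochondrion", organelle_index = 2L,
               analyte = "protein", concentration_mgml = m2))
  r <- correlate_between(prof, "mitochondrion", "protein",
                         "mitochondrion", "protein")
  expect_equal(r$n, n)
  expect_equal(r$r, cor(m1, m2))
})

test_that("Pearson r is invariant under positive affine maps", {
  set.seed(8)
  x <- rnorm(30, 50, 10); y <- 0.5 * x + rnorm(30, 0, 5)
  base <- make_profiles(list(nucleolus.protein = x, nucleolus.RNA = y))
  r0 <- correlate_within(base, "nucleolus", c("protein", "RNA"))$r
  scaled <- make_profiles(list(nucleolus.protein = 3 * x + 7,
                               nucleolus.RNA = 0.1 * y - 2))
  expect_equal(correlate_within(scaled, "nucleolus",
                                c("protein", "RNA"))$r, r0)
  flipped <- make_profiles(list(nucleolus.protein = -x, nucleolus.RNA = y))
  expect_equal(correlate_within(flipped, "nucleolus",
                                c("protein", "RNA"))$r, -r0)
})

test_that("two identical groups give F = 0 and p = 1", {
  prof <- rbind(make_profiles(list(nucleolus.protein = rep(5, 4)), "A"),
                make_profiles(list(nucleolus.protein = rep(5, 4)), "B"))
  a <- anova_between_lines(prof, "nucleolus", "protein")
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_false(a$significant)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(12)
  for (rep in 1:5) {
    ga <- rnorm(8, 50, 5); gb <- rnorm(11, 55, 5)
    prof <- rbind(make_profiles(list(ER.RNA = ga), "A"),
                  make_profiles(list(ER.RNA = gb), "B"))
    a <- anova_between_lines(prof, "ER", "RNA")
    t2 <- t.test(ga, gb, var.equal = TRUE)$statistic^2
    expect_equal(a$F, unname(t2), tolerance = 1e-9)
  }
  one <- make_profiles(list(ER.RNA = rnorm(5)), "A")
  expect_error(anova_between_lines(one, "ER", "RNA"), "2 cell-line groups")
})

test_that("the correlation matrix has the right shape and diagonal", {
  spec <- default_population_spec("WI38", n_cells = 30, seed = 4)
  pop <- simulate_population(spec)
  cm <- correlation_matrix(pop, organelles = c("nucleolus", "ER",
                                               "mitochondrion"),
                           analytes = c("protein", "RNA", "lipid"))
  # 9 variables: 9 diagonal entries + 36 unordered off-diagonal pairs
  expect_equal(nrow(cm), 45L)
  diag_rows <- cm$organelle_a == cm$organelle_b &
    cm$analyte_a == cm$analyte_b
  expect_equal(sum(diag_rows), 9L)
  expect_true(all(cm$r[diag_rows] == 1))
  expect_equal(sum(!diag_rows), 36L)
  expect_true(all(!is.na(cm$p_adj[!diag_rows])))

  # minimal scope: 2 analytes in 1 organelle -> 1 off-diagonal entry
  small <- correlation_matrix(pop, organelles = "nucleolus",
                              analytes = c("protein", "RNA"))
  expect_equal(nrow(small), 3L)
  expect_equal(sum(small$organelle_a == small$organelle_b &
                     small$analyte_a == small$analyte_b), 2L)
})
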