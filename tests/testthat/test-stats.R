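test_that("Levene statistic equals a hand-computed ANOVA on absolute deviations", {
  y <- c(1, 2, 3, 10, 20, 30)
  g <- rep(c("a", "b"), each = 3)
  lev <- leveneHomogeneity(y, g)
  # by hand: one-way ANOVA F on |y - group mean|
  d <- abs(y - ave(y, g))
  hand <- anova(lm(d ~ factor(g)))
  expect_equal(lev$statistic, hand[1, "F value"])
  expect_equal(lev$p, hand[1, "Pr(>F)"])
  expect_equal(lev$df, c(1, 4))
  expect_false(lev$degenerate)
})

test_that("Levene flags the degenerate all-constant case and bad inputs", {
  expect_warning(lev <- leveneHomogeneity(c(5, 5, 5, 9, 9, 9),
                                          rep(c("a", "b"), each = 3)),
                 "constant")
  expect_true(lev$degenerate)
  expect_true(is.nan(lev$statistic))
  expect_error(leveneHomogeneity(1:5, c("a", "a", "a", "a", "b")),
               "offending: b")
  expect_error(leveneHomogeneity(1:4, rep("a", 4)), "2 groups")
})

test_that("factorial ANOVA handles constant and noise-free responses", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- 5
  res <- factorialAnova(d, "y", c("A", "B"))
  expect_equal(res$statistic, c(0, 0, 0))
  expect_equal(res$p, c(1, 1, 1))

  # pure additive shift on A, zero noise
  d$y <- ifelse(d$A == "a2", 3, 0)
  res <- factorialAnova(d, "y", c("A", "B"))
  expect_equal(res$statistic[res$term == "A"], Inf)
  expect_equal(res$p[res$term == "A"], 0)
  expect_equal(res$statistic[res$term != "A"], c(0, 0))
})

test_that("factorial ANOVA matches the textbook decomposition on a balanced 2x2", {
  set.seed(21)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- 2 + (d$A == "a2") * 1.5 + (d$B == "b2") * -0.8 +
    (d$A == "a2" & d$B == "b2") * 0.5 + rnorm(12, 0, 0.3)
  res <- factorialAnova(d, "y", c("A", "B"))
  # balanced design: Type III equals the sequential decomposition
  ref <- anova(lm(y ~ A * B, data = d))
  expect_equal(res$statistic, ref[1:3, "F value"], tolerance = 1e-10)
  expect_equal(res$p, ref[1:3, "Pr(>F)"], tolerance = 1e-10)
  expect_equal(attr(res, "df_residual"), ref["Residuals", "Df"])
  # hand-computed main-effect sum of squares (cell-mean arithmetic)
  ssA <- 12 / 2 * sum((tapply(d$y, d$A, mean) - mean(d$y))^2) / 1
  expect_equal(res$sumsq[res$term == "A"], ssA, tolerance = 1e-10)
})

test_that("factorial ANOVA reproduces the car Type III table on unbalanced data", {
  set.seed(22)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"), rep = 1:4)
  d <- d[-c(1, 5, 9, 10), ]   # unbalance the cells
  d$y <- 1 + (d$A == "a2") * 0.9 - (d$B == "b3") * 0.7 + rnorm(nrow(d), 0, 0.5)
  mine <- factorialAnova(d, "y", c("A", "B"))
  ref <- car::Anova(lm(y ~ A * B, data = d,
                       contrasts = list(A = "contr.sum", B = "contr.sum")),
                    type = "III")
  keep <- setdiff(rownames(ref), c("(Intercept)", "Residuals"))
  expect_equal(mine$sumsq, ref[keep, "Sum Sq"], tolerance = 1e-10)
  expect_equal(mine$statistic, ref[keep, "F value"], tolerance = 1e-10)
  expect_equal(mine$p, ref[keep, "Pr(>F)"], tolerance = 1e-10)
})

test_that("factorial ANOVA names the empty cell that breaks an interaction", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- rnorm(12)
  d <- d[!(d$A == "a2" & d$B == "b2"), ]
  expect_error(factorialAnova(d, "y", c("A", "B")),
               "empty cell A=a2 x B=b2")
  expect_error(factorialAnova(d, "y", c("A", "missing")), "missing factor")
})

test_that("Tukey HSD agrees with the stats reference implementation", {
  set.seed(31)
  y <- c(rnorm(8, 0), rnorm(8, 1.2), rnorm(8, 0.4))
  g <- rep(c("g1", "g2", "g3"), each = 8)
  mine <- tukeyHsd(y, g)
  ref <- TukeyHSD(aov(y ~ factor(g)))$`factor(g)`
  expect_equal(sort(mine$comparisons$p_adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-10)
})

test_that("Tukey HSD letters separate an outlying group", {
  expect_warning(tukeyHsd(c(1, 1, 1, 9, 9, 9), rep(c("a", "b"), each = 3)),
                 "zero pooled SE")
  # zero within-group variance: a==b, c apart
  set.seed(5)
  y <- c(rnorm(6, 0, 0.01), rnorm(3, 9, 0.01))
  res <- tukeyHsd(y, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$letters[["a"]], res$letters[["b"]])
  expect_false(res$letters[["c"]] %in% res$letters[c("a", "b")])

  two <- tukeyHsd(rep(c(4, 4, 4, 4), 2), rep(c("a", "b"), each = 4))
  expect_equal(two$comparisons$statistic, 0)
  expect_equal(two$comparisons$p_adj, 1)
  expect_equal(two$letters[["a"]], two$letters[["b"]])
})

test_that("Games-Howell reduces to Tukey HSD for two groups with equal spread", {
  set.seed(41)
  x <- rnorm(15)
  y <- c(x, x + 1.1)   # identical sample variances by construction
  g <- rep(c("a", "b"), each = 15)
  gh <- gamesHowell(y, g)
  tk <- tukeyHsd(y, g)
  expect_equal(gh$comparisons$p_adj, tk$comparisons$p_adj, tolerance = 1e-6)
})

test_that("Games-Howell matches the Welch formulas on summary input", {
  summ <- data.frame(level = c("a", "b"), mean = c(0, 2),
                     sd = c(1, 3), n = c(10, 14))
  gh <- gamesHowell(summaries = summ)
  se2 <- 1 / 10 + 9 / 14
  tstat <- 2 / sqrt(se2)
  df <- se2^2 / ((1 / 10)^2 / 9 + (9 / 14)^2 / 13)
  expect_equal(gh$comparisons$statistic, tstat)
  expect_equal(gh$comparisons$df, df)
  expect_equal(gh$comparisons$p_adj,
               ptukey(tstat * sqrt(2), 2, df, lower.tail = FALSE))

  ident <- data.frame(level = c("a", "b"), mean = 1, sd = 0, n = 5)
  res <- gamesHowell(summaries = ident)
  expect_equal(res$comparisons$statistic, 0)
  expect_equal(res$comparisons$p_adj, 1)

  apart <- data.frame(level = c("a", "b"), mean = c(1, 2), sd = 0, n = 5)
  expect_warning(res <- gamesHowell(summaries = apart), "zero pooled SE")
  expect_equal(res$comparisons$p_adj, 0)
  expect_error(gamesHowell(summaries = data.frame(level = "a", mean = 1,
                                                  sd = 1, n = 1)), "n >= 2")
})

test_that("post hoc letters expose the n = 20 vs n = 40 sensitivity on printed day-14 summaries", {
  summ <- data.frame(level = c("A", "B", "C", "D", "E"),
                     mean = c(21.09, 20.73, 23.64, 24.83, 25.46),
                     sd = c(3.48, 2.85, 1.8, 1.79, 1.16))
  # measurement-level replication (2 colorimeter points x 20 fruits)
  l40 <- gamesHowell(summaries = transform(summ, n = 40))$letters
  expect_equal(unname(l40), c("a", "a", "b", "c", "c"))
  # fruit-level n = 20: C and D can no longer be separated
  l20 <- gamesHowell(summaries = transform(summ, n = 20))$letters
  expect_true(letterSharing(l20)["C", "D"])
  expect_false(letterSharing(l40)["C", "D"])
})

test_that("compact letters implement insert-and-absorb correctly", {
  lev <- c("A", "B", "C")
  mk <- function(vals) {
    p <- matrix(1, 3, 3, dimnames = list(lev, lev))
    p[lower.tri(p)] <- vals; p[upper.tri(p)] <- t(p)[upper.tri(p)]
    p
  }
  # all pairs significant -> all distinct
  expect_equal(unname(compactLetters(mk(c(0.01, 0.01, 0.01)))),
               c("a", "b", "c"))
  # nothing significant -> one shared letter
  expect_equal(unname(compactLetters(mk(c(0.5, 0.5, 0.5)))),
               c("a", "a", "a"))
  # chain A~B, B~C, A!~C
  expect_equal(unname(compactLetters(mk(c(0.5, 0.01, 0.5)))),
               c("a", "ab", "b"))
})

test_that("compact-letter sharing structure is invariant under level relabeling", {
  set.seed(51)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    lev <- LETTERS[1:k]
    p <- matrix(1, k, k, dimnames = list(lev, lev))
    vals <- sample(c(0.001, 0.2), k * (k - 1) / 2, replace = TRUE)
    p[lower.tri(p)] <- vals; p[upper.tri(p)] <- t(p)[upper.tri(p)]
    perm <- sample(k)
    p2 <- p[perm, perm]
    expect_identical(letterSharing(compactLetters(p)),
                     letterSharing(compactLetters(p2)))
    # sharing must agree with the pairwise decisions along the display rule:
    # significantly different levels never share a letter
    sh <- letterSharing(compactLetters(p))
    for (a in lev) for (b in lev)
      if (a != b && p[a, b] < 0.05) expect_false(sh[a, b])
  }
})

test_that("correlation matrices handle exact, monotone and degenerate cases", {
  d <- data.frame(x = 1:20)
  d$negx <- -d$x
  d$expx <- exp(d$x / 4)
  pe <- correlationMatrix(d, c("x", "negx", "expx"), "pearson")
  sp <- correlationMatrix(d, c("x", "negx", "expx"), "spearman")
  expect_equal(diag(pe$r), c(x = 1, negx = 1, expx = 1))
  expect_equal(pe$r["x", "negx"], -1)
  expect_equal(sp$r["x", "negx"], -1)
  expect_equal(sp$r["x", "expx"], 1)       # monotone nonlinear
  expect_lt(pe$r["x", "expx"], 1)
  expect_true(isSymmetric(pe$r))

  d$const <- 3
  expect_warning(cc <- correlationMatrix(d, c("x", "const"), "pearson"),
                 "constant feature")
  expect_true(is.na(cc$r["x", "const"]))
})

test_that("Spearman correlation is invariant to strictly monotone transforms", {
  set.seed(61)
  d <- data.frame(a = rnorm(40), b = rnorm(40))
  r0 <- correlationMatrix(d, c("a", "b"), "spearman")$r["a", "b"]
  d$a <- exp(2 * d$a); d$b <- atan(d$b)
  r1 <- correlationMatrix(d, c("a", "b"), "spearman")$r["a", "b"]
  expect_equal(r0, r1)
})
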