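test_that("assumption checks route normal data to the parametric branch", {
  nPar <- sum(vapply(1:200, function(s) {
    tab <- generateExperiment(nullGroupSpec(), seed = s)
    checkAssumptions(tab)$branch == "parametric"
  }, logical(1)))
  expect_gte(nPar / 200, 0.85)
})

test_that("variance heterogeneity and skew push data to the nonparametric branch", {
  # one cell with 10x the sd: Bartlett should fire with high probability
  spec10 <- nullGroupSpec()
  spec10$sd[1] <- 10
  nNp <- sum(vapply(1:100, function(s) {
    checkAssumptions(generateExperiment(spec10, seed = s))$branch ==
      "nonparametric"
  }, logical(1)))
  expect_gte(nNp / 100, 0.7)
  # exponential (heavily skewed) noise: routed nonparametric far more
  # often than the nominal false-switch rate under normal noise
  grid <- designGrid()
  rateExp <- mean(vapply(1:200, function(s) {
    set.seed(3000 + s)
    grid$response <- 5 + rexp(27)
    checkAssumptions(grid)$branch == "nonparametric"
  }, logical(1)))
  rateNorm <- mean(vapply(1:200, function(s) {
    checkAssumptions(generateExperiment(nullGroupSpec(), seed = s))$branch ==
      "nonparametric"
  }, logical(1)))
  expect_gte(rateExp, 0.25)
  expect_gt(rateExp, 2 * rateNorm)
})

test_that("two-way ANOVA detects the treatment effect of the transfection preset", {
  tab <- generateExperiment(groupSpecPreset("transfection"), seed = 1)
  a <- twoWayAnova(tab)
  expect_lt(a$pTreatment, 0.001)
  expect_true("treatment" %in% names(a$tukey))
  expect_true(all(a$tukey$treatment$`p adj` >= 0 &
                    a$tukey$treatment$`p adj` <= 1))
})

test_that("zero within-cell noise drives the treatment p-value to zero", {
  grid <- designGrid()
  grid$response <- ifelse(grid$treatment == "US+UCA", 5, 1)
  a <- twoWayAnova(grid)
  expect_equal(a$pTreatment, 0)
  expect_true(is.na(a$pTemperature))   # no temperature variation at all
})

test_that("unbalanced designs are refused", {
  tab <- generateExperiment(nullGroupSpec(), seed = 2)
  expect_error(twoWayAnova(tab[-1, ]), "balanced")
})

test_that("ANOVA p-value agrees with a permutation F-null", {
  grid <- designGrid()
  set.seed(77)
  grid$response <- rnorm(27, 5, 1)
  pAov <- twoWayAnova(grid)$pTreatment
  f0 <- summary(aov(response ~ treatment * temperature,
                    data = grid))[[1]][1, "F value"]
  perm <- vapply(1:2000, function(i) {
    g <- grid
    g$response <- sample(g$response)
    summary(aov(response ~ treatment * temperature,
                data = g))[[1]][1, "F value"]
  }, numeric(1))
  pPerm <- mean(perm >= f0)
  mcErr <- 3 * sqrt(pPerm * (1 - pPerm) / 2000)
  expect_lt(abs(pPerm - pAov), mcErr + 0.01)
})

test_that("completely separated treatments attain the maximal rank statistic", {
  grid <- designGrid()
  # responses ordered entirely by treatment
  base <- c("US+UCA" = 100, "US" = 50, "UCA" = 0)
  set.seed(88)
  grid$response <- base[grid$treatment] + runif(27, 0, 1)
  np <- nonparametricTests(grid)
  # closed-form maximal Kruskal-Wallis H for three groups of nine
  rbar <- c(mean(1:9), mean(10:18), mean(19:27))
  hMax <- 12 / (27 * 28) * sum(9 * (rbar - 14)^2)
  expect_equal(np$pTreatment, pchisq(hMax, df = 2, lower.tail = FALSE))
  # sampled assignments never exceed the separated arrangement
  for (i in 1:200) {
    g <- grid
    g$response <- sample(g$response)
    h <- kruskal.test(response ~ treatment, data = g)$statistic
    expect_lte(unname(h), hMax + 1e-9)
  }
  # significant factor gets a Holm-adjusted pairwise Wilcoxon table
  expect_true("treatment" %in% names(np$wilcoxon))
  expect_true(all(np$wilcoxon$treatment$pAdjusted >= 0 &
                    np$wilcoxon$treatment$pAdjusted <= 1))
})

test_that("decision-tree outputs are invariant to replicate relabelling", {
  tab <- generateExperiment(groupSpecPreset("cell_loss"), seed = 12)
  rep1 <- runDecisionTree(tab)
  set.seed(99)
  shuffled <- do.call(rbind, lapply(split(tab, list(tab$treatment,
                                                    tab$temperature)),
                                    function(d) d[sample(nrow(d)), ]))
  rep2 <- runDecisionTree(shuffled)
  expect_equal(rep1@branch, rep2@branch)
  expect_equal(rep1@pTreatment, rep2@pTreatment)
  expect_equal(rep1@pTemperature, rep2@pTemperature)
})

test_that("the decision tree records assumptions and routes the preset data", {
  tab <- generateExperiment(groupSpecPreset("transfection"), seed = 1)
  report <- runDecisionTree(tab)
  expect_true(report@branch %in% c("parametric", "nonparametric"))
  expect_lt(report@pTreatment, 0.001)
  if (report@branch == "nonparametric") expect_true(is.na(report@pInteraction))
  # degenerate inputs are refused
  grid <- designGrid()
  grid$response <- rep(1, 27)
  expect_error(checkAssumptions(grid), "degenerate")
  expect_error(nonparametricTests(grid), "tied")
  grid$response <- c("x")  # wrong type
  expect_error(asReplicateTable(grid), "numeric")
  bad <- designGrid()
  bad$response <- 1:27
  bad$treatment[1] <- "foo"
  expect_error(asReplicateTable(bad), "treatment levels")
})
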