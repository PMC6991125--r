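two_cell_table <- function() {
  data.frame(host = "H1", inoculum = rep(c("A", "B"), each = 3),
             vitamin = "replete", replicate = rep(1:3, 2),
             growth = c(1, 2, 3, 2, 3, 4), stringsAsFactors = FALSE)
}

test_that("cell-means model reproduces pooled two-sample arithmetic", {
  m <- cell_means(two_cell_table(), "growth")
  expect_equal(m$cells$mean, c(2, 3))
  expect_equal(m$cells$n, c(3L, 3L))
  expect_equal(m$sigma2, 1)       # (2 + 2) / 4
  expect_equal(m$df, 4L)
  # all responses equal -> zero pooled variance
  d0 <- two_cell_table(); d0$growth <- 5
  expect_equal(cell_means(d0, "growth")$sigma2, 0)
})

test_that("balanced full designs have df = N - cells and reproduce lm", {
  d <- response_table(seed = 7, reps = 3,
                      inoculums = c("A", "B", "C", "D", "E", "control"))
  m <- cell_means(d, "growth")
  expect_equal(m$df, 36L - 12L)
  lmfit <- lm(growth ~ inoculum * vitamin, data = d)
  expect_equal(m$sigma2, summary(lmfit)$sigma^2)
})

test_that("under-replicated cells and mixed-host tables are rejected", {
  d <- two_cell_table()[-(1:2), ]  # cell A left with a single replicate
  expect_error(cell_means(d, "growth"),
               class = "churchill_insufficient_replication")
  d2 <- rbind(two_cell_table(), transform(two_cell_table(), host = "H2"))
  expect_error(cell_means(d2, "growth"), class = "churchill_specification")
  expect_error(cell_means(two_cell_table(), "nope"),
               class = "churchill_specification")
})

test_that("non-converged replicates are excluded listwise", {
  d <- response_table(seed = 31)
  d$fit_converged[d$inoculum == "A" & d$vitamin == "replete"][1] <- FALSE
  m <- cell_means(d, "growth")
  cellA <- m$cells[m$cells$inoculum == "A" & m$cells$vitamin == "replete", ]
  expect_equal(cellA$n, 2L)
  expect_equal(m$df, 17L - 6L)
})

test_that("marginal means equal cell means with pooled-variance SEs", {
  d <- two_cell_table()
  m <- cell_means(d, "growth")
  mm <- marginal_means(m, c(inoculum = "B"))
  expect_equal(mm$mean, 3)
  expect_equal(mm$se, sqrt(1 / 3))
  # margin over two equal-n cells: simple average of the cell means
  expect_equal(marginal_means(m)$mean, 2.5)
  expect_error(marginal_means(m, c(inoculum = "Z")),
               class = "churchill_specification")
})

test_that("two-level contrasts reproduce the pooled two-sample t test", {
  m <- cell_means(two_cell_table(), "growth")
  pc <- pairwise_contrasts(m, "inoculum", within = c(vitamin = "replete"))
  expect_equal(pc$estimate, -1)
  expect_equal(pc$se, sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(pc$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(pc$df, 4L)
  oracle <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(pc$p_value, oracle$p.value)
  # family of size 1 is never adjusted
  expect_equal(pc$adj_p, pc$p_value)
  expect_equal(pc$family_size, 1L)
})

test_that("Tukey adjustment matches emmeans and is monotone in family size", {
  d <- response_table(seed = 13,
                      inoculums = c("A", "B", "C", "D", "E", "control"))
  m <- cell_means(d, "growth")
  pc <- pairwise_contrasts(m, "inoculum", within = c(vitamin = "replete"))
  expect_equal(nrow(pc), choose(6, 2))
  expect_true(all(pc$adj_p >= pc$p_value - 1e-12))
  expect_true(all(pc$adj_p <= 1))

  lmfit <- lm(growth ~ inoculum * vitamin, data = d)
  em <- summary(emmeans::contrast(emmeans::emmeans(lmfit, ~ inoculum | vitamin),
                                  "pairwise", adjust = "tukey"))
  em <- em[em$vitamin == "replete", ]
  expect_equal(pc$estimate, em$estimate, tolerance = 1e-10)
  expect_equal(pc$adj_p, em$p.value, tolerance = 1e-10)

  # the studentized-range p grows with the number of means compared
  padj <- vapply(2:6, function(k) ptukey(sqrt(2) * 2.1, k, 10,
                                         lower.tail = FALSE), 0)
  expect_true(all(diff(padj) > 0))
})

test_that("vitamin contrast is replete minus deficient, unadjusted", {
  d <- response_table(seed = 17)
  d$growth[d$inoculum == "control" & d$vitamin == "replete"] <- c(3, 3, 3)
  d$growth[d$inoculum == "control" & d$vitamin == "deficient"] <- c(1, 1, 1)
  m <- cell_means(d, "growth")
  vc <- vitamin_contrast(m, "control")
  expect_equal(vc$estimate, 2)
  expect_equal(vc$family_size, 1L)
  expect_equal(vc$adj_p, vc$p_value)
  expect_error(vitamin_contrast(m, "missing"),
               class = "churchill_specification")
  # planted vitamin effect is recovered within 3 SE
  d2 <- response_table(seed = 18, shift = data.frame(
    inoculum = "control", vitamin = "replete", response = "growth",
    delta = 0.005))
  vc2 <- vitamin_contrast(cell_means(d2, "growth"), "control")
  expect_lt(abs(vc2$estimate - 0.005), 3 * vc2$se)
})

test_that("percent impact behaves like a symmetric relative difference", {
  expect_equal(impact_percent(3, 1), 100)
  expect_equal(impact_percent(2, 2), 0)
  expect_error(impact_percent(1, -1), class = "churchill_undefined_impact")
  set.seed(19)
  a <- runif(50, 0.01, 10); b <- runif(50, 0.01, 10); cc <- runif(50, 0.1, 5)
  expect_equal(impact_percent(a, b), -impact_percent(b, a))
  expect_equal(impact_percent(cc * a, cc * b), impact_percent(a, b))
  expect_true(all(abs(impact_percent(a, b)) < 200))
})

test_that("impact direction follows the response semantics", {
  expect_identical(classify_direction("growth", 1), "beneficial")
  expect_identical(classify_direction("growth", -2), "detrimental")
  expect_identical(classify_direction("max_abundance", 0), "none")
  expect_identical(classify_direction("decline", 1), "detrimental")
  expect_identical(classify_direction("decline", -1), "beneficial")
  expect_error(classify_direction("lag", 1), class = "churchill_specification")
})

test_that("impact tables collect the right families and filter by alpha", {
  d <- response_table(seed = 23, sd = 5e-4,
                      inoculums = c("A", "B", "control"),
                      shift = data.frame(inoculum = "A", vitamin = "deficient",
                                         response = "growth", delta = -0.01))
  tabs <- build_impact_tables(d, alpha = 0.05)
  # planted depression of growth: significant, detrimental, vs control
  hit <- tabs$significant$inoculation
  hit <- hit[hit$response == "growth" & hit$a == "A" &
               hit$vitamin == "deficient", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$direction, "detrimental")
  expect_lt(hit$impact_percent, 0)
  expect_identical(hit$b, "control")
  # control rows are oriented inoculum-vs-control
  expect_false(any(tabs$full$inoculation$a == "control"))
  expect_true(all(tabs$full$inoculation$b == "control"))
  expect_false(any(tabs$full$pairwise$a == "control" |
                     tabs$full$pairwise$b == "control"))
  # per host and response: 2 vitamin levels x choose(3,2) pairs split 2/1,
  # and 3 vitamin contrasts
  expect_equal(nrow(tabs$full$inoculation), 3 * 2 * 2)
  expect_equal(nrow(tabs$full$pairwise), 3 * 2 * 1)
  expect_equal(nrow(tabs$full$vitamin), 3 * 3)
  # alpha = 1 keeps everything
  tabs1 <- build_impact_tables(d, alpha = 1)
  expect_equal(nrow(tabs1$significant$inoculation),
               nrow(tabs1$full$inoculation))
})

test_that("one-factor path mirrors one-way ANOVA for broth growth", {
  set.seed(29)
  d <- data.frame(host = "broth",
                  strain = rep(c("a2016", "a2024", "scs5"), each = 4),
                  vitamin = "broth", replicate = rep(1:4, 3),
                  growth = rnorm(12, 0.1, 0.01), stringsAsFactors = FALSE)
  m <- cell_means(d, "growth", factors = "strain")
  sm <- summary(m)
  aovfit <- summary(aov(growth ~ strain, data = d))[[1]]
  expect_equal(sm$F, aovfit[["F value"]][1])
  expect_equal(sm$p_value, aovfit[["Pr(>F)"]][1])
  pc <- pairwise_contrasts(m, "strain")
  expect_equal(nrow(pc), 3L)
  expect_equal(unique(pc$df), 9L)
})
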