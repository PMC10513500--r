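test_that("Cox coefficient matches the brute-force partial likelihood", {
  # hand-sized data, no ties
  tb <- data.frame(time = c(1.3, 2.1, 3.7, 4.2, 5.9, 6.5),
                   event = c(1, 1, 1, 0, 1, 1),
                   group = c("B", "A", "B", "A", "A", "B"))
  fit <- coxFit(tb, covariates = character())
  z <- as.integer(tb$group == "B")
  oracle <- stats::optimize(function(b)
    -coxPartialLogLik(b, tb$time, tb$event, z), c(-5, 5))$minimum
  expect_equal(fit$coefficients$coef[1L], oracle, tolerance = 1e-4)
  # second fixture with a different censoring pattern
  tb2 <- data.frame(time = c(0.5, 1.1, 1.9, 2.8, 3.3, 4.7, 5.2, 6.1),
                    event = c(1, 0, 1, 1, 1, 0, 1, 1),
                    group = c("A", "B", "B", "A", "B", "A", "A", "B"))
  fit2 <- coxFit(tb2, covariates = character())
  z2 <- as.integer(tb2$group == "B")
  oracle2 <- stats::optimize(function(b)
    -coxPartialLogLik(b, tb2$time, tb2$event, z2), c(-5, 5))$minimum
  expect_equal(fit2$coefficients$coef[1L], oracle2, tolerance = 1e-4)
  expect_equal(fit2$coefficients$HR[1L], exp(oracle2), tolerance = 1e-3)
})

test_that("Cox fit validates its inputs", {
  tb <- handSurvival()
  tb$age <- 5
  expect_error(coxFit(tb, covariates = "age"), "zero variance")
  expect_error(coxFit(data.frame(time = c(-1, 2), event = c(1, 0),
                                 group = c("A", "B")),
                      covariates = character()), "> 0")
  expect_warning(coxFit(transform(handSurvival(), age = rnorm(8)),
                        covariates = "age"), "events")
})

test_that("null simulations center the hazard ratio at 1", {
  logs <- vapply(1:20, function(s) {
    sp <- syntheticSpec(classCounts = c(A = 5L, B = 5L), nProbes = 10L,
                        nInformative = 2L, nGenes = 5L, censorRate = 0.2,
                        seed = 100L + s)
    sv <- generateSurvival(factor(rep(c("A", "B"), each = 500L)), sp)
    sv$group <- withr::with_seed(s, sample(sv$subgroup))
    coxFit(sv, covariates = character())$coefficients$coef[1L]
  }, numeric(1L))
  expect_lt(median(abs(logs)), 0.1)
})

test_that("dichotomization picks a cut-off that recovers the effect", {
  withr::with_seed(41L, {
    n <- 500L
    marker <- runif(n)
    hazard <- 0.1 * ifelse(marker > median(marker), 3, 1)
    time <- rexp(n, hazard)
    cens <- rexp(n, 0.03)
    tb <- data.frame(time = pmin(time, cens),
                     event = as.integer(time <= cens),
                     age = rnorm(n, 10, 3),
                     sex = sample(c("M", "F"), n, TRUE))
    res <- dichotomizeBest(marker, tb, covariates = c("age", "sex"))
    expect_true(res$cutoff %in% c("mean", "median"))
    gi <- grep("^group", res$fit$coefficients$term)[1L]
    expect_gt(res$fit$coefficients$HR[gi], 2)
    expect_lt(res$fit$coefficients$HR[gi], 4.5)
    expect_equal(as.vector(table(res$group)), c(250L, 250L))
    # a constant marker leaves every candidate with an empty group
    expect_error(dichotomizeBest(rep(0.5, n), tb), "group-size floor")
  })
})

test_that("the quartile candidates respect the group-size floor", {
  withr::with_seed(42L, {
    n <- 100L
    # three-quarters of the mass at one value: only some cut-offs are legal
    marker <- c(rep(0.1, 75L), runif(25L, 0.6, 0.9))
    tb <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1L, 0.8))
    res <- dichotomizeBest(marker, tb, covariates = character(),
                           minGroupFrac = 0.2)
    expect_gte(min(table(res$group)), 20L)
  })
})

test_that("log-rank matches the observed-minus-expected hand computation", {
  tb <- handSurvival()
  lr <- logrank(tb, tb$group)
  oracle <- logrankByHand(tb$time, tb$event, tb$group)
  expect_equal(lr$statistic, oracle, tolerance = 1e-6)
  expect_equal(lr$p, pchisq(oracle, 1L, lower.tail = FALSE), tolerance = 1e-6)
  # identical survival in both groups: statistic 0, p 1
  tb2 <- data.frame(time = rep(c(1, 2, 3), 2L), event = rep(1L, 6L),
                    group = rep(c("A", "B"), each = 3L))
  lr2 <- logrank(tb2, tb2$group)
  expect_equal(lr2$statistic, 0)
  expect_equal(lr2$p, 1)
  # a strong effect is detected
  withr::with_seed(43L, {
    n <- 200L
    g <- rep(c("lo", "hi"), each = n / 2L)
    tm <- rexp(n, 0.1 * ifelse(g == "hi", 5, 1))
    tb3 <- data.frame(time = tm, event = 1L)
    expect_lt(logrank(tb3, g)$p, 0.05)
  })
  expect_error(logrank(tb, rep("A", 8L)), "2 groups")
})

test_that("log-rank p-values are uniform under the null", {
  ps <- vapply(1:200, function(s) withr::with_seed(1000L + s, {
    n <- 60L
    tb <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1L, 0.8))
    logrank(tb, sample(rep(c("A", "B"), each = n / 2L)))$p
  }), numeric(1L))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("Kaplan-Meier curves are valid product-limit estimates", {
  # all events at times 1, 2, 3: survival 2/3, 1/3, 0
  tb <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- kmCurve(tb)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # no events: flat at 1
  tbC <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_true(all(kmCurve(tbC)$surv == 1))
  # censoring after the last event leaves the curve constant
  tbX <- data.frame(time = c(1, 2, 5, 6), event = c(1, 1, 0, 0))
  kmX <- kmCurve(tbX)
  expect_equal(kmX$surv[kmX$time >= 2], rep(0.5, 3L))
  # general validity: in [0,1], non-increasing per group, starts <= 1
  withr::with_seed(44L, {
    tb2 <- data.frame(time = rexp(50L, 0.2), event = rbinom(50L, 1L, 0.7))
    g <- rep(c("A", "B"), 25L)
    km2 <- kmCurve(tb2, g)
    for (gr in c("A", "B")) {
      s <- km2$surv[km2$group == gr][order(km2$time[km2$group == gr])]
      expect_true(all(s >= 0 & s <= 1))
      expect_true(all(diff(s) <= 1e-12))
    }
  })
})

test_that("the marker screen tabulates HR and p-values per marker", {
  withr::with_seed(45L, {
    n <- 120L
    markers <- matrix(runif(3L * n), 3L, n,
                      dimnames = list(paste0("cg", 1:3), NULL))
    hazard <- 0.1 * ifelse(markers[1L, ] > median(markers[1L, ]), 4, 1)
    time <- rexp(n, hazard)
    tb <- data.frame(time = time, event = 1L)
    scr <- survivalScreen(markers, tb, covariates = character())
    expect_equal(nrow(scr), 3L)
    expect_named(scr, c("marker", "cutoff", "HR", "lower95", "upper95",
                        "wald_p", "lr_p", "logrank_p"))
    expect_lt(scr$logrank_p[1L], 0.05)   # the real biomarker is flagged
    expect_gt(scr$HR[1L], 2)
  })
})
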