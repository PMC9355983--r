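test_that("caliper tumor volume formula", {
  expect_equal(tumor_volume(1, 1), 0.52)
  w <- c(2, 3.5, 7)
  expect_equal(tumor_volume(w, w), 0.52 * w^3)
  expect_equal(tumor_volume(5, 10), 130)  # 0.52 * 25 * 10
  expect_error(tumor_volume(0, 1), "positive")
  expect_error(tumor_volume(2, -1), "positive")
  # strictly increasing in each dimension
  expect_true(tumor_volume(2.1, 3) > tumor_volume(2, 3))
  expect_true(tumor_volume(2, 3.1) > tumor_volume(2, 3))
})

test_that("%TGI trivial, regression and invariance cases", {
  g <- two_day_growth(list(c1 = c(150, 350), c2 = c(150, 350),
                           t1 = c(150, 350), t2 = c(150, 350)),
                      list(c1 = "vehicle", c2 = "vehicle",
                           t1 = "drug", t2 = "drug"))
  expect_equal(percent_tgi(g, "drug", "vehicle")$tgi_percent, 0)

  g2 <- two_day_growth(list(c1 = c(150, 350), c2 = c(150, 350),
                            t1 = c(200, 200), t2 = c(200, 200)),
                       list(c1 = "vehicle", c2 = "vehicle",
                            t1 = "drug", t2 = "drug"))
  expect_equal(percent_tgi(g2, "drug", "vehicle")$tgi_percent, 100)

  # regression beyond stasis: control 150 -> 350, treated 200 -> 180
  g3 <- two_day_growth(list(c1 = c(150, 350), c2 = c(150, 350),
                            t1 = c(200, 180), t2 = c(200, 180)),
                       list(c1 = "vehicle", c2 = "vehicle",
                            t1 = "drug", t2 = "drug"))
  r3 <- percent_tgi(g3, "drug", "vehicle")
  expect_equal(r3$tgi_percent, 110)

  # rescaling all volumes leaves %TGI unchanged
  g4 <- g3; g4$volume <- g4$volume * 7.3
  expect_equal(percent_tgi(g4, "drug", "vehicle")$tgi_percent, 110)

  # flat control arm: undefined
  g5 <- two_day_growth(list(c1 = c(150, 150), c2 = c(150, 150),
                            t1 = c(200, 180), t2 = c(200, 180)),
                       list(c1 = "vehicle", c2 = "vehicle",
                            t1 = "drug", t2 = "drug"))
  expect_error(percent_tgi(g5, "drug", "vehicle"), "undefined")
})

test_that("%TGI excludes animals missing an endpoint, with a warning", {
  rows <- rbind(
    data.frame(animal_id = "c1", group = "vehicle", day = c(0, 21),
               width = 1, length = 1, volume = c(150, 350)),
    data.frame(animal_id = "c2", group = "vehicle", day = c(0, 21),
               width = 1, length = 1, volume = c(150, 350)),
    data.frame(animal_id = "t1", group = "drug", day = c(0, 21),
               width = 1, length = 1, volume = c(200, 180)),
    data.frame(animal_id = "t2", group = "drug", day = c(0, 14),
               width = 1, length = 1, volume = c(999, 999)))
  g <- as_growth_table(rows)
  expect_warning(r <- percent_tgi(g, "drug", "vehicle", final_day = 21), "t2")
  expect_equal(r$tgi_percent, 110)
  expect_equal(r$n_treated, 1)
})

test_that("growth slopes: closed forms and normal-equations oracle", {
  days <- c(0, 4, 7, 11, 14)
  v <- 180 * exp(0.08 * days)
  g <- as_growth_table(data.frame(animal_id = "a1", group = "g", day = days,
                                  width = 1, length = 1, volume = v))
  fit <- growth_slopes(g)
  expect_equal(fit$slope, 0.08, tolerance = 1e-14)
  expect_equal(fit$intercept, log(180), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # two points: slope = delta ln V / delta day exactly
  g2 <- two_day_growth(list(a = c(100, 400)), list(a = "g"), days = c(3, 10))
  expect_equal(growth_slopes(g2)$slope, log(4) / 7)

  # random noisy curves vs an independent normal-equations oracle
  set.seed(30)
  for (rep in 1:5) {
    d <- sort(sample(0:28, 6))
    vol <- exp(rnorm(6, 5, 0.4))
    g3 <- as_growth_table(data.frame(animal_id = "x", group = "g", day = d,
                                     width = 1, length = 1, volume = vol))
    y <- log(vol)
    slope_oracle <- sum((d - mean(d)) * (y - mean(y))) / sum((d - mean(d))^2)
    expect_equal(growth_slopes(g3)$slope, slope_oracle, tolerance = 1e-10)
  }

  # time-shift invariance of the slope
  g4 <- as_growth_table(data.frame(animal_id = "x", group = "g", day = d + 5,
                                   width = 1, length = 1, volume = vol))
  expect_equal(growth_slopes(g4)$slope, growth_slopes(g3)$slope,
               tolerance = 1e-12)
})

test_that("ANOVA/Tukey: degenerate equality, two-group q = sqrt(2) |t| link", {
  slopes <- data.frame(slope = rep(c(0.1, 0.12, 0.09), 3),
                       group = rep(c("a", "b", "c"), each = 3))
  cmp <- anova_tukey(slopes)
  expect_equal(cmp$anova_F, 0)
  expect_true(all(cmp$pairwise$adjusted_p == 1))
  expect_equal(nrow(cmp$pairwise), 3L)

  set.seed(31)
  s1 <- rnorm(6, 0.10, 0.02); s2 <- rnorm(5, 0.05, 0.02)
  two <- data.frame(slope = c(s1, s2),
                    group = rep(c("vehicle", "drug"), c(6, 5)))
  cmp2 <- anova_tukey(two)
  tt <- t.test(s1, s2, var.equal = TRUE)
  p_link <- ptukey(sqrt(2) * abs(tt$statistic), 2, 9, lower.tail = FALSE)
  expect_equal(cmp2$pairwise$adjusted_p, unname(p_link), tolerance = 1e-6)
  # two-group Tukey p also equals the pooled t-test p
  expect_equal(cmp2$pairwise$adjusted_p, tt$p.value, tolerance = 1e-6)

  expect_error(anova_tukey(data.frame(slope = 1:3,
                                      group = c("a", "a", "b"))),
               "< 2 animals")
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise p-values", {
  set.seed(32)
  slopes <- data.frame(slope = rnorm(15, 0.1, 0.03),
                       group = rep(c("a", "b", "c"), each = 5))
  cmp <- anova_tukey(slopes)
  for (i in seq_len(nrow(cmp$pairwise))) {
    gi <- cmp$pairwise$group_i[i]; gj <- cmp$pairwise$group_j[i]
    p_raw <- t.test(slopes$slope[slopes$group == gi],
                    slopes$slope[slopes$group == gj],
                    var.equal = TRUE)$p.value
    expect_gte(cmp$pairwise$adjusted_p[i], p_raw - 1e-10)
  }
})

test_that("ddCt fold changes: identities and error paths", {
  ct <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    condition = rep(c("control", "treated"), each = 3),
    gene = rep(c("HEY1", "MYC", "ACTB"), 2),
    ct = c(25, 27, 18, 25, 27, 18),
    is_reference = rep(c(FALSE, FALSE, TRUE), 2))
  fc <- ddct_fold_change(as_ct_table(ct))
  expect_equal(fc$fold_change, c(1, 1))

  ct2 <- ct; ct2$ct[4] <- 24  # HEY1 one cycle lower in treated
  fc2 <- ddct_fold_change(as_ct_table(ct2))
  expect_equal(fc2$fold_change[fc2$gene == "HEY1"], 2)

  # reference shift alone does not change folds
  ct3 <- ct; ct3$ct[ct3$condition == "treated"] <- ct3$ct[ct3$condition == "treated"] + 1
  expect_equal(ddct_fold_change(as_ct_table(ct3))$fold_change, c(1, 1))

  ct4 <- ct[ct$gene != "ACTB" | ct$condition != "treated", ]
  expect_error(ddct_fold_change(ct4), "reference")
})

test_that("noisy triplicate simulation recovers a strong knockdown", {
  ct <- simulate_ct_table(100, c("HEY1", "NRARP"), c(0.25, 0.25),
                          noise_sd = 0.2, seed = 33)
  fc <- ddct_fold_change(ct)
  expect_true(all(abs(fc$fold_change - 0.25) < 0.05))
})
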