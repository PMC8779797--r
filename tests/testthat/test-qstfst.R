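test_that("log2 conversion is exact and rejects non-positive abundances", {
  vals <- matrix(c(3, 0, 0, 0), nrow = 2,
                 dimnames = list(c("a1", "a2"), c("m1", "m2")))
  m <- make_metab(vals, reps = 2)
  lt <- log2_transform(m)
  expect_true(lt$log2)
  expect_equal(lt$data$abundance[lt$data$accession == "a1" &
                                   lt$data$metabolite == "m1"], c(3, 3))
  expect_equal(lt$data$abundance[lt$data$metabolite == "m2"], rep(0, 4))
  expect_error(log2_transform(lt), "already")

  bad <- m
  bad$data$abundance[5] <- 0
  expect_error(log2_transform(bad), "non-positive abundance at accession")
})

test_that("variance components match the expected-mean-squares oracle", {
  # identical means, zero within variance -> (0, 0)
  v0 <- matrix(1, nrow = 6, ncol = 1,
               dimnames = list(sprintf("a%d", 1:6), "m1"))
  m0 <- log2_transform(make_metab(v0))
  gr <- group_assignment(sprintf("a%d", 1:6), rep(c("X", "Y"), each = 3))
  vc0 <- variance_components(m0, gr, c("X", "Y"))
  expect_equal(vc0$sigma_b2, 0)
  expect_equal(vc0$sigma_w2, 0)

  # balanced toy: {0,0,0} vs {2,2,2} -> all variance between, Qst = 1
  v1 <- matrix(rep(c(0, 2), each = 3), nrow = 6,
               dimnames = list(sprintf("a%d", 1:6), "m1"))
  m1 <- log2_transform(make_metab(v1))
  vc1 <- variance_components(m1, gr, c("X", "Y"))
  expect_equal(vc1$sigma_w2, 0)
  expect_gt(vc1$sigma_b2, 0)
  expect_equal(qst(vc1$sigma_b2, vc1$sigma_w2), 1)

  # random instances, balanced and unbalanced, vs the aov-based oracle
  set.seed(31)
  for (k in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    y <- rnorm(n1 + n2, rep(c(0, 1), c(n1, n2)))
    acc <- sprintf("a%d", seq_along(y))
    vm <- matrix(y, ncol = 1, dimnames = list(acc, "m1"))
    mm <- log2_transform(make_metab(vm))
    grk <- group_assignment(acc, rep(c("X", "Y"), c(n1, n2)))
    vck <- variance_components(mm, grk, c("X", "Y"))
    orc <- vc_oracle(y, rep(c("X", "Y"), c(n1, n2)))
    expect_equal(vck$sigma_b2, orc$sigma_b2)
    expect_equal(vck$sigma_w2, orc$sigma_w2)
  }
})

test_that("variance components agree with a mixed-model fit when interior", {
  # for a balanced one-way design with a positive between-group estimate the
  # method-of-moments solution equals the REML mixed-model answer
  set.seed(41)
  y <- rnorm(12, rep(c(0, 3), each = 6))
  acc <- sprintf("a%d", 1:12)
  gr <- group_assignment(acc, rep(c("X", "Y"), each = 6))
  vm <- matrix(y, ncol = 1, dimnames = list(acc, "m1"))
  vc <- variance_components(log2_transform(make_metab(vm)), gr, c("X", "Y"))
  fit <- lme4::lmer(y ~ 1 + (1 | g),
                    data = data.frame(y = y, g = rep(c("X", "Y"), each = 6)))
  vcl <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$sigma_b2, vcl$vcov[vcl$grp == "g"], tolerance = 1e-4)
  expect_equal(vc$sigma_w2, vcl$vcov[vcl$grp == "Residual"], tolerance = 1e-4)
})

test_that("Qst evaluates its defining ratio with the edge conventions", {
  expect_equal(qst(2, 1), 0.5)
  expect_equal(qst(0, 1), 0)
  expect_equal(qst(3, 0.5), 0.75)
  expect_true(is.na(qst(0, 0)))
  expect_error(qst(-1, 1), "non-negative")
})

test_that("bootstrap CIs degenerate correctly and respect the seed", {
  v <- matrix(rep(c(0, 2), each = 4), nrow = 8,
              dimnames = list(sprintf("a%d", 1:8), "m1"))
  m <- log2_transform(make_metab(v))
  gr <- group_assignment(sprintf("a%d", 1:8), rep(c("X", "Y"), each = 4))
  ci <- bootstrap_qst_ci(m, gr, c("X", "Y"), n_boot = 50, seed = 3)
  # zero within-group variance, distinct means: every resample gives Qst 1
  expect_equal(ci$ci_lo, 1)
  expect_equal(ci$ci_hi, 1)

  set.seed(51)
  v2 <- matrix(rnorm(16), nrow = 8,
               dimnames = list(sprintf("a%d", 1:8), c("m1", "m2")))
  m2 <- log2_transform(make_metab(v2))
  c1 <- bootstrap_qst_ci(m2, gr, c("X", "Y"), n_boot = 100, seed = 9)
  c2 <- bootstrap_qst_ci(m2, gr, c("X", "Y"), n_boot = 100, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$ci_lo <= c1$ci_hi))
})

test_that("divergence calls compare the whole CI to the reference, strictly", {
  expect_true(call_divergent(0.5, 0.3))
  expect_false(call_divergent(0.1, 0.3))
  expect_false(call_divergent(0.3, 0.3))  # boundary: not divergent
  expect_true(is.na(call_divergent(NA, 0.3)))
})

test_that("stage set algebra satisfies inclusion-exclusion", {
  v <- stage_venn(c("m1", "m2"), c("m2", "m3"), universe = 10)
  expect_equal(v$n_common, 1)
  expect_equal(v$n_union, 3)
  expect_equal(v$percent_common_of_all, 10)

  vd <- stage_venn(c("a", "b"), c("c"), universe = c("a", "b", "c", "d"))
  expect_equal(vd$n_common, 0)
  expect_equal(vd$n_union, vd$n_stage1 + vd$n_stage2)

  set.seed(61)
  for (k in 1:10) {
    u <- sprintf("m%03d", 1:50)
    s1 <- sample(u, sample(0:30, 1))
    s2 <- sample(u, sample(0:30, 1))
    v <- stage_venn(s1, s2, u)
    expect_equal(v$n_union, v$n_stage1 + v$n_stage2 - v$n_common)
  }
})

test_that("class summaries tabulate divergent metabolites by stage", {
  ann <- data.frame(metabolite = c("m1", "m2", "m3"),
                    class = c("alkaloids", "alkaloids", "vitamins"))
  cs <- class_summary(list(s1 = c("m1", "m2"), s2 = character(0)), ann)
  expect_equal(cs$stage_specific[cs$class == "alkaloids"], "s1")

  expect_equal(nrow(class_summary(list(s1 = character(0),
                                       s2 = character(0)), ann)), 0)

  # unannotated metabolites fall into "unclassified"
  cs2 <- class_summary(list(s1 = "mX", s2 = c("m3", "mX")), ann)
  expect_equal(cs2$s2[cs2$class == "unclassified"], 1)
  expect_equal(cs2$stage_specific[cs2$class == "vitamins"], "s2")

  # randomized annotation vs a direct group-by
  set.seed(71)
  for (k in 1:5) {
    ids <- sprintf("m%02d", 1:30)
    annk <- data.frame(metabolite = ids,
                       class = sample(c("c1", "c2", "c3"), 30, replace = TRUE))
    s1 <- sample(ids, 10); s2 <- sample(ids, 12)
    csk <- class_summary(list(s1 = s1, s2 = s2), annk)
    for (cl in csk$class) {
      expect_equal(csk$s1[csk$class == cl],
                   sum(annk$class[match(s1, annk$metabolite)] == cl))
    }
  }
})
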