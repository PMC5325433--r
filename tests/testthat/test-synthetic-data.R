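test_that("expression fixtures are deterministic in the seed", {
  cfg <- expression_fixture_config(n_probes = 300, seed = 1)
  a <- generate_expression_fixture(cfg)
  b <- generate_expression_fixture(cfg)
  expect_identical(a$values, b$values)
  expect_identical(attr(a, "roles"), attr(b, "roles"))
  c2 <- generate_expression_fixture(
    expression_fixture_config(n_probes = 300, seed = 2))
  expect_false(identical(a$values, c2$values))
})

test_that("the screen on a fixture recovers exactly the planted set", {
  for (seed in c(3, 17)) {
    cfg <- expression_fixture_config(n_probes = 500, seed = seed)
    em <- generate_expression_fixture(cfg)
    thr <- screen_thresholds()
    res <- screen(em, thr)
    expect_identical(res$selected_probes, attr(em, "planted_probes"))
    expect_length(res$selected_probes, 3)
    # cross-check with the independent brute-force filter
    expect_identical(brute_force_screen(em, thr), attr(em, "planted_probes"))
    # decoys fail exactly their designated criterion
    roles <- attr(em, "roles")
    tab <- res$table
    expect_true(all(!tab$pass_normal[roles[tab$probe_id] == "normal_leaky"]))
    expect_true(all(tab$pass_tumor[roles[tab$probe_id] == "normal_leaky"]))
    expect_true(all(!tab$pass_tumor[roles[tab$probe_id] == "tumor_weak"]))
    expect_true(all(tab$pass_normal[roles[tab$probe_id] == "tumor_weak"]))
    expect_true(all(!tab$pass_tumor[roles[tab$probe_id] == "tumor_rare"]))
  }
})

test_that("planting zero markers yields an empty screen", {
  em <- generate_expression_fixture(
    expression_fixture_config(n_probes = 400, n_planted_markers = 0,
                              seed = 5))
  expect_length(screen(em)$selected_probes, 0)
})

test_that("impossible fixture configs are rejected", {
  expect_error(expression_fixture_config(n_probes = 10,
                                         n_planted_markers = 6,
                                         decoy_counts = c(tumor_weak = 5)),
               "exceed n_probes")
  expect_error(expression_fixture_config(background_log_sd = 0), "log_sd")
  expect_error(
    generate_expression_fixture(
      expression_fixture_config(n_probes = 50, n_tumors = 10, seed = 1)),
    "tumor_rank_k")
})

test_that("TMA fixtures respect score bounds, duplicates and noise", {
  cfg <- tma_fixture_config(n_cases = 40, seed = 6)
  fix <- generate_tma_fixture(cfg)
  cores <- fix$cores
  expect_true(all(cores$score %in% 0:10))
  expect_true(all(cores$marker %in% c("CDH17", "CLDN18", "CLDN7")))
  # duplicate-core noise bound
  key <- paste(cores$case_id, cores$marker, cores$site)
  for (k in unique(key)) {
    s <- cores$score[key == k]
    if (length(s) == 2) expect_lte(abs(diff(s)), cfg$replicate_noise)
  }
  # determinism
  expect_identical(fix$cores, generate_tma_fixture(cfg)$cores)
})

test_that("no missing LN cores means four cores per case and marker", {
  fix <- generate_tma_fixture(
    tma_fixture_config(n_cases = 25, missing_ln_core_rate = 0, seed = 7))
  counts <- table(fix$cores$case_id, fix$cores$marker)
  expect_true(all(counts == 4))
})

test_that("zero replicate noise gives identical duplicate cores", {
  fix <- generate_tma_fixture(
    tma_fixture_config(n_cases = 25, replicate_noise = 0, seed = 8))
  key <- paste(fix$cores$case_id, fix$cores$marker, fix$cores$site)
  for (k in unique(key)) {
    s <- fix$cores$score[key == k]
    if (length(s) == 2) expect_equal(s[1], s[2])
  }
})

test_that("the classifier recovers the latent groups of TMA fixtures", {
  fix <- generate_tma_fixture(
    tma_fixture_config(n_cases = 60, seed = 9))
  cls <- classify_cases(aggregate_cores(fix$cores))
  merged <- merge(cls, fix$latent_groups, by = "case_id")
  expect_equal(merged$group.x, merged$group.y)

  pure <- generate_tma_fixture(
    tma_fixture_config(n_cases = 30, group_proportions = c(1, 0, 0, 0),
                       seed = 10))
  cls_pure <- classify_cases(aggregate_cores(pure$cores))
  expect_true(all(cls_pure$group == "Group1"))
})

test_that("invalid TMA weights are rejected", {
  expect_error(tma_fixture_config(group_proportions = c(-1, 1, 0, 0)),
               "non-negative")
  expect_error(tma_fixture_config(group_proportions = c(0, 0, 0, 0)),
               "positive")
})

test_that("uncensored exponential survival has median ln(2)/rate", {
  cfg <- survival_fixture_config(group_hazards = c(g = 0.01),
                                 censor_rate = 0, max_followup = 1e9,
                                 seed = 11)
  sv <- generate_survival_fixture(cfg, rep("g", 10000))
  expect_true(all(sv$event == 1))
  expect_equal(median(sv$time), log(2) / 0.01, tolerance = 0.06)
})

test_that("survival fixture censoring and label checks behave", {
  cfg <- survival_fixture_config(group_hazards = c(a = 1e-4, b = 5e-4),
                                 censor_rate = 0, max_followup = 0.001,
                                 seed = 12)
  sv <- generate_survival_fixture(cfg, rep(c("a", "b"), 20))
  expect_true(all(sv$time <= 0.001))
  expect_true(all(sv$event == 0))
  expect_error(generate_survival_fixture(cfg, c("a", "zz")), "zz")
  expect_identical(generate_survival_fixture(cfg, rep("a", 5)),
                   generate_survival_fixture(cfg, rep("a", 5)))
  expect_error(survival_fixture_config(group_hazards = c(a = 0)),
               "group_hazards > 0")
})

test_that("the Gehan test holds its nominal level on null survival fixtures", {
  set.seed(13)
  n_rep <- 400
  rej <- replicate(n_rep, {
    t <- rexp(60, 0.01); cen <- rexp(60, 0.003)
    gehan_wilcoxon_test(pmin(t, cen), as.integer(t <= cen),
                        rep(c("a", "b"), each = 30))$p_value < 0.05
  })
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 4 * se)
})
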