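base_stats <- function(...) {
  st <- list(mean_ctl_p1 = 50, mean_ctl_p7 = 40, sem_ctl_p7 = 5,
             mean_mi_p7 = 100, sem_mi_p7 = 5,
             mean_ctl_p28 = 40, sem_ctl_p28 = 5,
             mean_mi_p28 = 40, sem_mi_p28 = 5,
             raw_total = 5000)
  utils::modifyList(st, list(...))
}

test_that("abundance filter is inclusive at the 200-count boundary", {
  counts <- matrix(c(50L, 50L, 50L, 50L, 0L, 0L), nrow = 1,
                   dimnames = list("g", paste0("s", 1:6)))
  d <- data.frame(sample_id = paste0("s", 1:6),
                  condition = rep(c("CTL", "MI"), each = 3),
                  timepoint = "P7", replicate = rep(1:3, 2))
  m <- count_matrix(counts, d)
  expect_true(passes_abundance(m, "g"))                      # total exactly 200
  expect_false(passes_abundance(m, "g", classifier_config(min_raw_total = 201)))
  expect_true(passes_abundance(m, "g", classifier_config(min_raw_total = 0)))
  expect_error(passes_abundance(m, "nope"), "unknown gene")
})

test_that("early call requires fold, strict bar separation and flat controls", {
  cfg <- classifier_config()
  # canonical positive: 100 +/- 5 vs 40 +/- 5, controls declining
  expect_true(apply_gene_criteria(base_stats(), cfg)$early_up)
  # wide MI bars still separated: lower 60 > upper 45
  expect_true(apply_gene_criteria(base_stats(sem_mi_p7 = 40), cfg)$early_up)
  # overlap: lower 40 < upper 45
  expect_false(apply_gene_criteria(base_stats(sem_mi_p7 = 60), cfg)$early_up)
  # control rose from P1 to P7
  expect_false(apply_gene_criteria(base_stats(mean_ctl_p1 = 20), cfg)$early_up)
  # equality of control means is allowed ("no increase")
  expect_true(apply_gene_criteria(base_stats(mean_ctl_p1 = 40), cfg)$early_up)
  # missing CTL-P1 disables the early call rather than erroring
  expect_false(apply_gene_criteria(base_stats(mean_ctl_p1 = NA), cfg)$early_up)
})

test_that("relaxed configurations drop individual early clauses", {
  overlap <- base_stats(sem_mi_p7 = 60)
  expect_true(apply_gene_criteria(
    overlap, classifier_config(require_error_bar_separation_p7 = FALSE))$early_up)
  rising <- base_stats(mean_ctl_p1 = 20)
  expect_true(apply_gene_criteria(
    rising, classifier_config(require_control_nonincrease = FALSE))$early_up)
  # tolerance knob: a 10% control rise passes at control_tolerance 0.25
  slight <- base_stats(mean_ctl_p1 = 40, mean_ctl_p7 = 44,
                       mean_mi_p7 = 110)
  expect_false(apply_gene_criteria(slight, classifier_config())$early_up)
  expect_true(apply_gene_criteria(
    slight, classifier_config(control_tolerance = 0.25))$early_up)
})

test_that("late calls are fold-only and late_down mirrors late_up", {
  cfg <- classifier_config()
  # overlapping bars at P28 do not block the late call
  late <- apply_gene_criteria(
    base_stats(mean_mi_p28 = 100, sem_mi_p28 = 50, sem_ctl_p28 = 50), cfg)
  expect_true(late$late_up)
  expect_false(late$late_down)
  # strict mode adds the separation requirement at P28
  expect_false(apply_gene_criteria(
    base_stats(mean_mi_p28 = 100, sem_mi_p28 = 50, sem_ctl_p28 = 50),
    classifier_config(strict_late_separation = TRUE))$late_up)
  # late_down: CTL at least two-fold above MI
  dn <- apply_gene_criteria(base_stats(mean_mi_p28 = 10, mean_ctl_p28 = 30), cfg)
  expect_true(dn$late_down)
  expect_false(dn$late_up)
  # nested mode restricts late to early genes
  lateonly <- base_stats(mean_mi_p7 = 40, mean_mi_p28 = 100)
  expect_true(apply_gene_criteria(lateonly, cfg)$late_up)
  expect_false(apply_gene_criteria(
    lateonly, classifier_config(late_requires_early = TRUE))$late_up)
})

test_that("classify_gene agrees with the criteria core on real matrices", {
  cm <- rand_cm(10, seed = 5)
  sums <- summarize_groups(cm)
  for (g in rownames(cm$counts)[1:5]) {
    row <- classify_gene(sums, cm, g)
    full <- classify_all(cm, with_concordance = FALSE)
    expect_equal(row$early_up, full$early_up[full$gene_id == g])
    expect_equal(row$late_up, full$late_up[full$gene_id == g])
    expect_equal(row$late_down, full$late_down[full$gene_id == g])
  }
})

test_that("classify_all handles planted and degenerate matrices", {
  # exactly one early gene by construction
  mu <- matrix(100, nrow = 3, ncol = 15)
  mu[1, ] <- rep(c(200, 100, 100, 400, 100), each = 3)   # planted early
  mu[2, ] <- rep(c(100, 100, 100, 150, 100), each = 3)   # subthreshold
  cm <- make_cm(matrix(as.integer(mu), nrow = 3))
  st <- classify_all(cm)
  expect_equal(st$early_up, c(TRUE, FALSE, FALSE))
  expect_true(all(!st$late_up))
  # concordance annotation: gene 1 is fully separated at P7 (400 vs 100)
  expect_equal(st$p_concordance_P7[1], 0.5^9)
  expect_equal(st$p_rank_P7[1], 0.05)

  # all-zero matrix: every flag false, no error
  zero <- make_cm(matrix(0L, nrow = 2, ncol = 15))
  expect_warning(stz <- classify_all(zero), "unit size factors")
  expect_true(all(!stz$early_up & !stz$late_up & !stz$late_down &
                    !stz$passes_abundance))
})

test_that("raising MI-P7 expression never revokes an early call", {
  set.seed(42)
  cfg <- classifier_config(min_raw_total = 0)
  for (i in 1:200) {
    st <- base_stats(mean_ctl_p7 = runif(1, 10, 100),
                     sem_ctl_p7 = runif(1, 0, 30),
                     mean_mi_p7 = runif(1, 10, 300),
                     sem_mi_p7 = runif(1, 0, 60),
                     mean_ctl_p1 = runif(1, 10, 120),
                     raw_total = 1000)
    before <- apply_gene_criteria(st, cfg)$early_up
    st$mean_mi_p7 <- st$mean_mi_p7 + runif(1, 0, 200)
    after <- apply_gene_criteria(st, cfg)$early_up
    if (before) expect_true(after)
  }
})

test_that("statuses survive rescaling a sample except through raw counts", {
  cm <- rand_cm(20, seed = 9)
  scaled <- cm$counts
  scaled[, 2] <- scaled[, 2] * 3L
  cm2 <- count_matrix(scaled, cm$design)
  # with the abundance filter disabled the calls are identical
  cfg0 <- classifier_config(min_raw_total = 0)
  s1 <- classify_all(cm, cfg0, with_concordance = FALSE)
  s2 <- classify_all(cm2, cfg0, with_concordance = FALSE)
  expect_equal(s1$early_up, s2$early_up)
  expect_equal(s1$late_up, s2$late_up)
  # fold changes move only through the pseudocount's interaction with the
  # global renormalization constant; the group-mean ratios are exact
  expect_equal(s1$log2fc_P7, s2$log2fc_P7, tolerance = 1e-2)
  r1 <- summarize_groups(cm); r2 <- summarize_groups(cm2)
  expect_equal(r2$mean_norm / r1$mean_norm,
               rep((r2$mean_norm / r1$mean_norm)[1], nrow(r1)),
               tolerance = 1e-9)
  # the raw-count abundance filter is deliberately not scale-invariant
  t1 <- sum(cm$counts[1, ]); t2 <- sum(cm2$counts[1, ])
  expect_true(t2 > t1)
})
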