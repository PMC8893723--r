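test_that("generators are seed-deterministic and seed-sensitive", {
  a <- gen_expression(100, seed = 5)
  b <- gen_expression(100, seed = 5)
  c <- gen_expression(100, seed = 6)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expr$values, c$expr$values))

  x <- gen_allele_counts(100, seed = 5)
  y <- gen_allele_counts(100, seed = 5)
  z <- gen_allele_counts(100, seed = 6)
  expect_identical(x$counts, y$counts)
  expect_false(identical(x$counts, z$counts))
})

test_that("generated tables pass the core validators", {
  sim <- gen_expression(50, seed = 2)
  expect_s3_class(sim$expr, "fs_expression")
  expect_true(all(sim$expr$values >= 0))
  ac <- gen_allele_counts(50, seed = 2)
  expect_s3_class(ac$counts, "fs_allele_counts")
  # truth invariant: planted_fc = 1 <=> not developmental
  expect_equal(sim$truth$planted_fc > 1, sim$truth$is_developmental)
})

test_that("expression generator: noiseless limit and null limit", {
  # noise 0, planted FC 8: every planted gene recovered exactly
  s0 <- gen_expression(300, frac_dev = 0.3, fc_range = c(8, 8),
                       noise_sd = 0, frac_vm_max = 0, seed = 3)
  dev <- classify_developmental(s0$expr, fc_threshold = 4)
  expect_equal(dev$is_dev, s0$truth$is_developmental)
  expect_equal(dev$max_fc[s0$truth$is_developmental],
               rep(8, sum(s0$truth$is_developmental)))
  # frac_dev 0: false positives bounded by noise (none at FC >= 4)
  null <- gen_expression(500, frac_dev = 0, frac_vm_max = 0,
                         noise_sd = 0.25, seed = 4)
  devn <- classify_developmental(null$expr, fc_threshold = 4)
  expect_lte(mean(devn$is_dev), 0.005)
  # VM-boosted genes exercise the exclusion rule
  vm <- gen_expression(400, frac_dev = 0, frac_vm_max = 0.25,
                       noise_sd = 0.1, seed = 5)
  dvm <- classify_developmental(vm$expr, fc_threshold = 4)
  expect_gt(mean(dvm$excluded_vm[vm$truth$vm_max]), 0.9)
  expect_true(all(!dvm$is_dev[dvm$excluded_vm]))
  expect_error(gen_expression(10, design = default_design()[0, ]), "empty")
})

test_that("allele-count generator hits its stated world", {
  ac <- gen_allele_counts(500, depth_mean = 200, seed = 7)
  # class mix and ratio bands respect the truth invariants
  with(ac$truth, {
    expect_true(all(true_as_ratio[true_class == "EE"] == 0.5))
    m <- pmax(true_as_ratio, 1 - true_as_ratio)
    expect_true(all(m[true_class == "S2"] > 0.69 - 1e-9 &
                    m[true_class == "S2"] <= 0.80))
    expect_true(all(m[true_class == "S4"] > 0.80))
  })
  # indecisive_frac 1 masks every gene to AS 0.5 downstream
  all_ind <- gen_allele_counts(50, indecisive_frac = 1, seed = 8)
  r <- compute_as_ratio(all_ind$counts)
  expect_true(all(r$as == 0.5))
  expect_true(all(r$masked))
  # empirical AS approaches truth at high depth
  deep <- gen_allele_counts(200, depth_mean = 5000, indecisive_frac = 0,
                            seed = 9)
  rd <- compute_as_ratio(deep$counts)
  m <- merge(aggregate(as ~ gene, rd, mean), deep$truth, by = "gene")
  expect_lt(max(abs(m$as - m$true_as_ratio)), 0.05)
  expect_error(gen_allele_counts(10, depth_mean = 0), "positive")
})

test_that("read generator: noiseless limits and error enumeration bound", {
  v <- variant_table(rep("c1", 60), seq(1, 60 * 30, by = 30),
                     rep(c("A", "C", "G", "T"), length.out = 60),
                     rep(c("G", "T", "A", "C"), length.out = 60))
  # error 0: true parent recovered for every read with >= 1 SNP
  r0 <- gen_reads(v, read_len = 300, n_reads = 400, error_rate = 0,
                  parent_mix = 0.5, seed = 3)
  asn <- assign_reads_from_obs(r0$obs, v)
  m <- merge(asn, r0$truth, by = "read_id")
  expect_true(all((m$call == "parentA") == (m$true_parent == "A")))
  # parent_mix 1: no read assigned to parent B
  r1 <- gen_reads(v, read_len = 300, n_reads = 200, error_rate = 0,
                  parent_mix = 1, seed = 4)
  a1 <- assign_reads_from_obs(r1$obs, v)
  expect_false(any(a1$call == "parentB"))

  # error 0.01: misassignment below the analytic bound from enumerating
  # error patterns.  A read from parent A with k covered SNPs, ne errors
  # of which nb land on the B allele (prob 1/3 each), has hd_a = ne and
  # hd_b = k - nb; a wrong call needs hd_b < hd_a, hd_b <= 1 (else both
  # distances exceed 1) and hd_a <= 15.
  e <- 0.01
  p_wrong_k <- function(k) {
    tot <- 0
    for (ne in 0:k) for (nb in 0:ne) {
      if ((k - nb) < ne && (k - nb) <= 1 && ne <= 15)
        tot <- tot + dbinom(ne, k, e) * dbinom(nb, ne, 1 / 3)
    }
    tot
  }
  r2 <- gen_reads(v, read_len = 300, n_reads = 10000, error_rate = 0.01,
                  parent_mix = 0.5, seed = 3)
  a2 <- assign_reads_from_obs(r2$obs, v)
  m2 <- merge(a2, r2$truth, by = "read_id")
  wrong <- (m2$call == "parentA" & m2$true_parent == "B") |
           (m2$call == "parentB" & m2$true_parent == "A")
  bound <- mean(vapply(m2$n_sites.y, p_wrong_k, numeric(1)))
  expect_lte(mean(wrong), bound + 3 * sqrt(bound / length(wrong)) + 2e-4)
})

test_that("orthogroup generator: birth/loss semantics", {
  tr <- fix_tree7()
  # loss 0 -> exact age recovery
  og0 <- gen_orthogroups(tr, 150, loss_prob = 0, seed = 5)
  a0 <- assign_gene_ages(og0$og_table, tr)
  m0 <- merge(a0, og0$truth, by = "orthogroup")
  expect_equal(mean(m0$age == m0$true_age), 1)
  # birth at the focal tip -> presence only in the focal species
  tipborn <- og0$truth$birth_node == match("F", tr$tree$tip.label)
  for (o in og0$truth$orthogroup[tipborn])
    expect_equal(og0$og_table$species[og0$og_table$orthogroup == o], "F")
  # loss > 0 -> inferred age >= true age, focal always present
  og2 <- gen_orthogroups(tr, 150, loss_prob = 0.2, seed = 5)
  a2 <- assign_gene_ages(og2$og_table, tr)
  m2 <- merge(a2, og2$truth, by = "orthogroup")
  expect_true(all(m2$age >= m2$true_age))
  expect_true(all(tapply(og2$og_table$species, og2$og_table$orthogroup,
                         function(s) "F" %in% s)))
  expect_error(gen_orthogroups(tr, 10, loss_prob = 1), "loss_prob")
})
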