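test_that("read assignment implements the three indecisiveness rules", {
  r <- assign_read(c(0, 2, 1, 0, 16, 0), c(3, 5, 1, 16, 16, 0))
  expect_equal(r$call, c("parentA", "indecisive", "indecisive", "indecisive",
                         "indecisive", "indecisive"))
  expect_equal(r$reason, c("none", "both_gt1", "tie", "too_divergent",
                           "both_gt1", "tie"))
  # 'closer' variant of the divergence rule rescues (0, 16)
  r2 <- assign_read(0, 16, divergent_rule = "closer")
  expect_equal(r2$call, "parentA")
})

test_that("assignment matches the rule truth table over [0,20]^2", {
  g <- expand.grid(a = 0:20, b = 0:20)
  got <- assign_read(g$a, g$b)
  want <- t(mapply(oracle_assign_read, g$a, g$b))
  expect_equal(got$call, unname(want[, 1]))
  expect_equal(got$reason, unname(want[, 2]))
  decisive <- got$call != "indecisive"
  expect_true(all(pmin(g$a, g$b)[decisive] <= 1))
  expect_true(all(pmax(g$a, g$b)[decisive] <= 15))
})

test_that("per-read observations aggregate into distances correctly", {
  v <- variant_table(rep("c1", 4), c(10, 20, 30, 40),
                     c("A", "C", "G", "T"), c("G", "T", "A", "C"))
  obs <- data.frame(read_id = c("r1", "r1", "r1", "r2", "r2"),
                    contig = "c1", position = c(10, 20, 30, 10, 20),
                    base = c("A", "C", "A", "G", "T"),
                    phred = c(40, 40, 40, 40, 25))
  asn <- assign_reads_from_obs(obs, v)
  # r1: matches A at 2 sites, B at 1 -> hd_a 1, hd_b 2 -> parent A
  expect_equal(asn$hd_a[asn$read_id == "r1"], 1L)
  expect_equal(asn$call[asn$read_id == "r1"], "parentA")
  # r2: second base fails Phred 30, leaving one B-matching site
  expect_equal(asn$n_sites[asn$read_id == "r2"], 1L)
  expect_equal(asn$call[asn$read_id == "r2"], "parentB")
})

test_that("AS ratios mask exactly per the published rules", {
  counts <- allele_count_table(data.frame(
    gene = paste0("g", 1:5), sample = "s1",
    count_a = c(30, 10, 80, 30, 0),
    count_b = c(10, 4, 20, 10, 0),
    count_indecisive = c(5, 0, 500, 5, 0),
    fpkm_total = c(10, 10, 50, 1.5, 0)))
  r <- compute_as_ratio(counts)
  expect_equal(r$as[1], 0.75); expect_false(r$masked[1])
  expect_equal(r$mask_reason[2], "few_decisive")       # 14 decisive
  expect_equal(r$mask_reason[3], "indecisive_dominant") # 500/600 > 0.8
  expect_equal(r$mask_reason[4], "low_fpkm")            # FPKM < 2
  expect_true(all(r$as[r$masked] == 0.5))
  expect_equal(r$mask_reason[5], "low_fpkm")
})

make_as_tab <- function(reps_by_gene, design) {
  do.call(rbind, lapply(names(reps_by_gene), function(g) {
    a <- reps_by_gene[[g]]
    data.frame(gene = g, sample = design$sample_id[seq_along(a)],
               as = a, masked = FALSE, mask_reason = "none",
               stringsAsFactors = FALSE)
  }))
}

test_that("EE/S2/S4 classification follows the geometric-mean bands", {
  des <- sample_design(paste0("P1_", 1:3), rep("P1", 3), NA, 1:3, FALSE)
  tab <- make_as_tab(list(
    s4 = c(0.85, 0.90, 0.82),   # gm 0.8566 > 0.8
    s2 = c(0.70, 0.70, 0.69),   # gm 0.6968 in (0.68, 0.8]
    ee = c(0.5, 0.5, 0.5),
    mix = c(0.9, 0.4, 0.9),     # sides disagree -> EE
    s4b = c(0.12, 0.10, 0.15)), des)
  res <- classify_ase(tab, des)
  cls <- setNames(res$class, res$gene)
  expect_equal(unname(cls[c("s4", "s2", "ee", "mix", "s4b")]),
               c("S4", "S2", "EE", "EE", "S4"))
  expect_equal(res$direction[res$gene == "s4"], "A")
  expect_equal(res$direction[res$gene == "s4b"], "B")
  # masked replicate counts as unbiased and blocks the group
  tab$masked[tab$gene == "s4" & tab$sample == "P1_2"] <- TRUE
  res2 <- classify_ase(tab, des)
  expect_equal(res2$class[res2$gene == "s4"], "EE")
})

test_that("classes partition the genes; band widening is monotone; mirror", {
  set.seed(21)
  sim <- gen_allele_counts(400, depth_mean = 150, seed = 21)
  as_tab <- compute_as_ratio(sim$counts)
  des <- default_design()
  res <- classify_ase(as_tab, des)
  expect_setequal(res$gene, unique(sim$counts$gene))     # partition covers
  expect_true(all(res$class %in% c("EE", "S2", "S4")))   # and is exclusive
  # widening the S4 band toward 0.5 never shrinks the S4 set
  wide <- classify_ase(as_tab, des, s4_band = c(0.3, 0.7))
  expect_true(all(res$gene[res$class == "S4"] %in%
                  wide$gene[wide$class == "S4"]))
  # swapping parents mirrors AS and directions but keeps membership
  mir <- as_tab; mir$as <- 1 - mir$as
  rm_ <- classify_ase(mir, des)
  expect_equal(rm_$class, res$class)
  swap <- c(A = "B", B = "A", none = "none")
  expect_equal(unname(swap[res$direction]), rm_$direction)
})

test_that("CRR and NRR are grouped FPKM ratios", {
  genes <- paste0("g", 1:6)
  fa <- setNames(c(2, 4, 6, 1, 3, 5), genes)
  fb <- setNames(c(1, 2, 3, 1, 3, 5), genes)
  ctg <- setNames(rep(c("chr1", "chr2"), each = 3), genes)
  r <- compute_crr_nrr(fa, fb, ctg)
  expect_equal(r$crr$crr, c(2, 1))     # chr1: 12/6; chr2: 9/9
  expect_equal(r$nrr, 21 / 15)
  # identical vectors -> all 1; scaling -> constant ratio
  expect_equal(compute_crr_nrr(fa, fa, ctg)$nrr, 1)
  expect_equal(compute_crr_nrr(2 * fb, fb, ctg)$crr$crr, c(2, 2))
  # zero denominator -> missing
  fb0 <- fb; fb0[1:3] <- 0
  expect_true(is.na(compute_crr_nrr(fa, fb0, ctg)$crr$crr[1]))
  # random table vs independent groupby-sum oracle
  set.seed(22)
  fa2 <- setNames(runif(30, 0, 50), paste0("x", 1:30))
  fb2 <- setNames(runif(30, 1, 50), paste0("x", 1:30))
  c2 <- setNames(sample(paste0("chr", 1:4), 30, replace = TRUE),
                 paste0("x", 1:30))
  got <- compute_crr_nrr(fa2, fb2, c2)
  for (ch in unique(c2)) {
    expect_equal(got$crr$crr[got$crr$contig == ch],
                 sum(fa2[c2 == ch]) / sum(fb2[c2 == ch]))
  }
})
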