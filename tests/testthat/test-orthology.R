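mk_hits <- function(query, target, bitscore, evalue = 1e-50) {
  hit_table(data.frame(query = query, target = target, bitscore = bitscore,
                       evalue = evalue, nident = 100, alnlen = 120,
                       qlen = 150, slen = 150))
}

test_that("asymmetric coverage filter keeps fragments, drops aspecific hits", {
  h <- hit_table(data.frame(
    query = c("p1", "p2", "p3"), target = c("q1", "q2", "q3"),
    bitscore = 100, evalue = 1e-10, nident = 1,
    alnlen = c(90, 70, 200), qlen = c(100, 100, 200),
    slen = c(400, 100, 200)))
  # p1: longer cov 90/400=0.225 >= 0.2, shorter 0.9 >= 0.8 -> kept
  # p2: equal lengths, cov 0.7 < 0.8 -> dropped
  # p3: equal lengths full-length -> kept
  out <- coverage_filter(h)
  expect_equal(out$query, c("p1", "p3"))
  expect_error(coverage_filter(transform(h, qlen = 0)), "zero-length")
})

test_that("MCL: disjoint cliques stay separate, single edge is one cluster", {
  v <- c("a", "b", "c", "x", "y", "z")
  w <- matrix(0, 6, 6, dimnames = list(v, v))
  w["a", "b"] <- w["b", "c"] <- w["a", "c"] <- 1
  w["x", "y"] <- w["y", "z"] <- w["x", "z"] <- 1
  w <- pmax(w, t(w))
  cl <- mcl_cluster(w)
  expect_equal(length(cl), 2L)
  expect_equal(cl[[1]], c("a", "b", "c"))
  expect_equal(cl[[2]], c("x", "y", "z"))

  e <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mcl_cluster(e), list(`1` = c("a", "b")))
})

test_that("MCL matches the independent reference on a 12-vertex barbell", {
  v <- c(paste0("l", 1:6), paste0("r", 1:6))
  b <- matrix(0, 12, 12, dimnames = list(v, v))
  for (i in 1:6) for (j in 1:6) if (i < j) { b[i, j] <- 1; b[i + 6, j + 6] <- 1 }
  b["l6", "r1"] <- 1
  b <- pmax(b, t(b))
  got <- mcl_cluster(b, inflation = 2)
  ref <- oracle_mcl(b, inflation = 2)
  expect_equal(unname(got), unname(ref))
  # every cluster sits inside one connected component; vertices covered once
  expect_setequal(unlist(got), v)
  expect_equal(anyDuplicated(unlist(got)), 0L)
})

test_that("RBH groups form only on reciprocal best hits", {
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  # a1<->b1 reciprocal; a2's best is b2 but b2's best is a1 -> no pair
  h <- mk_hits(c("a1", "b1", "a2", "b2", "b2"),
               c("b1", "a1", "b2", "a1", "a2"),
               c(300, 300, 200, 250, 200))
  g <- build_rbh_groups(h, sp, "A")
  expect_equal(g$member[g$group == "a1"], c("a1", "b1"))
  expect_false("a2" %in% g$group)         # reciprocity violated
  # e-value cutoff removes hits entirely
  g2 <- build_rbh_groups(h, sp, "A", evalue_cutoff = 1e-60)
  expect_equal(nrow(g2), 0L)
})

test_that("RBH output is invariant to hit-table row order (brute force)", {
  set.seed(41)
  species <- setNames(rep(c("A", "B", "C"), each = 4),
                      paste0(rep(c("a", "b", "c"), each = 4), 1:4))
  prot <- names(species)
  pairs <- expand.grid(q = prot, t = prot, stringsAsFactors = FALSE)
  pairs <- pairs[species[pairs$q] != species[pairs$t], ]
  keep <- runif(nrow(pairs)) < 0.6
  h <- mk_hits(pairs$q[keep], pairs$t[keep],
               round(runif(sum(keep), 50, 400)))
  g1 <- build_rbh_groups(h, species, "A")
  g2 <- build_rbh_groups(h[sample(nrow(h)), ], species, "A")
  expect_equal(g1, g2)
  # brute-force reciprocity check of every reported pair
  best_of <- function(q, tsp) {
    cand <- h[h$query == q & species[h$target] == tsp, ]
    if (!nrow(cand)) return(NA_character_)
    cand$target[order(-cand$bitscore, cand$evalue, cand$target)][1]
  }
  for (i in which(g1$member != g1$group)) {
    s <- g1$group[i]; m <- g1$member[i]
    expect_equal(best_of(s, species[m]), m)
    expect_equal(best_of(m, "A"), s)
  }
})

test_that("spurious-member filter applies the conjunction, iterated", {
  grp <- data.frame(group = "s", member = c("s", "m1", "m2", "m3"),
                    species = c("A", "B", "C", "D"),
                    bitscore = c(NA, 350, 350, 100),
                    hit_overlap = c(1, 0.9, 0.9, 0.4))
  out <- filter_spurious_members(grp)
  expect_false("m3" %in% out$member)      # 100 < 350/3 and overlap 0.4 < 0.5
  grp$bitscore[4] <- 200
  expect_equal(nrow(filter_spurious_members(grp)), 4L)  # 200 >= 350/3
  grp$bitscore[4] <- 100; grp$hit_overlap[4] <- 0.6
  expect_equal(nrow(filter_spurious_members(grp)), 4L)  # conjunction fails
  two <- grp[1:2, ]
  expect_equal(filter_spurious_members(two), two)       # 2-member unchanged
})

test_that("conserved classification and the shared/CM split", {
  og_dev <- rbind(
    data.frame(orthogroup = "o1", species = paste0("s", 1:9),
               present = TRUE, is_dev = c(rep(TRUE, 5), rep(FALSE, 4))),
    data.frame(orthogroup = "o2", species = paste0("s", 1:9),
               present = TRUE, is_dev = c(rep(TRUE, 4), rep(FALSE, 5))),
    data.frame(orthogroup = "o3", species = paste0("s", 1:9),
               present = TRUE, is_dev = FALSE))
  cc <- classify_conserved(og_dev)
  expect_equal(setNames(cc$conserved, cc$orthogroup),
               c(o1 = TRUE, o2 = FALSE, o3 = FALSE))  # 4/9 < 0.5
  # all-species denominator mode
  og4 <- data.frame(orthogroup = "o4", species = paste0("s", 1:5),
                    present = TRUE, is_dev = TRUE)
  expect_true(classify_conserved(og4)$conserved)
  expect_false(classify_conserved(og4, denominator = "all",
                                  n_all = 11)$conserved)
  # monotone: adding a developmental species never de-conserves
  og_dev2 <- og_dev
  og_dev2$is_dev[og_dev2$orthogroup == "o2" & og_dev2$species == "s5"] <- TRUE
  cc2 <- classify_conserved(og_dev2)
  expect_true(all(cc2$conserved >= cc$conserved))
  expect_error(classify_conserved(
    data.frame(orthogroup = "o9", species = "s1", present = FALSE,
               is_dev = NA)), "nowhere")

  split <- split_shared_cm(cc, c(o1 = "dev", o2 = "absent", o3 = "nondev"))
  expect_equal(setNames(split$category, split$orthogroup),
               c(o1 = "shared", o2 = "nonconserved", o3 = "nonconserved"))
  split2 <- split_shared_cm(transform(cc, conserved = TRUE),
                            c(o1 = "dev", o2 = "absent", o3 = "nondev"))
  expect_equal(split2$category, c("shared", "cm_missing", "cm_nondev"))
  # category additivity over the conserved set
  expect_equal(sum(split2$category %in%
                     c("shared", "cm_missing", "cm_nondev")),
               sum(split2$conserved))
})

test_that("planted orthogroup-origin enrichment is detected", {
  set.seed(42)
  n <- 500
  ogs <- paste0("og", 1:n)
  ages <- setNames(sample(1:10, n, replace = TRUE), ogs)
  cls <- data.frame(orthogroup = ogs, conserved = TRUE,
                    category = "shared", stringsAsFactors = FALSE)
  planted <- ages == 6 & seq_len(n) %% 2 == 0
  cls$category[planted] <- "cm_missing"
  enr <- og_origin_enrichment(cls, ages)
  hit <- enr[enr$age == 6, ]
  expect_gt(hit$odds_ratio, 1)
  expect_lt(hit$fdr, 0.05)
  # distributed identically to background -> OR 1
  cls2 <- cls; cls2$category <- rep(c("cm_missing", "shared"), length.out = n)
  a2 <- setNames(rep(1:2, each = n / 2), ogs)
  enr2 <- og_origin_enrichment(cls2, a2)
  expect_equal(enr2$odds_ratio, c(1, 1))
  expect_equal(enr2$p, c(1, 1))
})

test_that("upstream identity: global alignment percent identity", {
  s <- paste(rep("ACGT", 300), collapse = "")
  expect_equal(upstream_identity(s, s), 100)
  expect_equal(upstream_identity("ACGTACGTAC", "ACGTACGTAA"), 90)
  a <- "ACGTTGCAAC"; b <- "AGGTTGCAAC"
  expect_equal(upstream_identity(a, b), upstream_identity(b, a))
  expect_error(upstream_identity("ACGT", "AC-T"), "non-ACGTN")
  expect_error(upstream_identity("", "ACGT"), "empty")
})
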