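# Independent oracles, deliberately coded apart from the package
# implementations they check.

# --- Hamming-rule truth table: literal transcription of the three
#     indecisiveness rules, applied in order, scalar if/else ------------
oracle_assign_read <- function(hd_a, hd_b, dec = 1, div = 15) {
  if (hd_a > dec && hd_b > dec) return(c("indecisive", "both_gt1"))
  if (hd_a > div || hd_b > div) return(c("indecisive", "too_divergent"))
  if (hd_a == hd_b) return(c("indecisive", "tie"))
  if (hd_a < hd_b) c("parentA", "none") else c("parentB", "none")
}

# --- two-sided Fisher p by direct hypergeometric summation ------------
# margins (a+b, c+d, a+c) fixed; sum the probabilities of all tables no
# more probable than the observed one (same relErr guard as fisher.test)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(lp)
  p_obs <- p[x == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# --- Benjamini-Hochberg by the step-up definition ---------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# --- all permutations of 1..n (n small) -------------------------------
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

mk_s <- function(v) {
  s <- 0
  for (i in seq_along(v)) for (j in seq_along(v)) if (j > i)
    s <- s + sign(v[j] - v[i])
  s
}

# exact two-sided Mann-Kendall p by exhausting all n! orderings
oracle_mk_p <- function(values) {
  n <- length(values)
  P <- all_perms(n)
  s_obs <- abs(mk_s(values))
  hits <- 0
  for (r in seq_len(nrow(P)))
    if (abs(mk_s(values[P[r, ]])) >= s_obs) hits <- hits + 1
  hits / nrow(P)
}

# --- reference MCL: same mathematics, independent code path -----------
# (row-major loops, Frobenius convergence, attractor-based cluster
# read-out instead of connected components)
oracle_mcl <- function(w, inflation = 2, iters = 200) {
  n <- nrow(w)
  for (i in seq_len(n)) {
    mx <- max(w[i, -i], 0)
    w[i, i] <- if (mx > 0) mx else 1
  }
  for (j in seq_len(n)) w[, j] <- w[, j] / sum(w[, j])
  for (it in seq_len(iters)) {
    m2 <- w %*% w
    m2 <- m2 ^ inflation
    for (j in seq_len(n)) m2[, j] <- m2[, j] / sum(m2[, j])
    if (sqrt(sum((m2 - w)^2)) < 1e-10) { w <- m2; break }
    w <- m2
  }
  attractors <- which(diag(w) > 1e-6)
  clusters <- lapply(attractors, function(a) sort(rownames(w)[w[a, ] > 1e-6]))
  clusters <- unique(clusters)
  # merge overlapping attractor systems
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j && length(intersect(clusters[[i]], clusters[[j]]))) {
        clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
        clusters[[j]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  clusters[order(vapply(clusters, `[[`, "", 1))]
}

# --- brute-force gene age: deepest common ancestor over root paths ----
oracle_gene_age <- function(og_species, stree) {
  tree <- stree$tree
  root <- length(tree$tip.label) + 1L
  paths <- lapply(og_species, function(sp)
    ape::nodepath(tree, root, match(sp, tree$tip.label)))
  common <- Reduce(intersect, paths)
  mrca <- common[length(common)]           # deepest shared node
  # project onto the focal path
  anc <- ape::nodepath(tree, root, match(stree$focal, tree$tip.label))
  p <- mrca
  parents <- integer(max(tree$edge))
  parents[tree$edge[, 2]] <- tree$edge[, 1]
  while (!(p %in% anc)) p <- parents[p]
  match(p, anc)
}

# --- site classification truth table (independent coding) -------------
oracle_classify_site <- function(base, aa, ab, phred, min_phred = 30) {
  if (phred < min_phred || base == "N") return("discarded_quality")
  if (aa == ab) {
    if (base == aa) "match" else "both_diff"
  } else {
    if (base == aa || base == ab) "allele_marker" else "both_diff"
  }
}
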