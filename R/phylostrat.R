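## Phylostratigraphic gene ages on a rooted species tree, transcriptome
## age indices (TAI), and age-stratified enrichment statistics.
##
## Ages are node numbers on the root-to-focal-tip path, numbered 1 at the
## root and increasing toward the focal species; the focal tip itself is
## the youngest stratum K.  A gene's age is the path node at which the
## MRCA of the species carrying its orthogroup attaches to that path.

#' Build a numbered species tree around a focal species
#'
#' @param tree a rooted `ape::phylo` object (or path to a Newick file).
#' @param focal tip label of the focal species.
#' @return object of class `fs_tree`: the phylo, the focal tip, the
#'   root-to-tip path as internal node ids, and `K` (number of path
#'   nodes, i.e. the youngest age).
#' @export
species_tree <- function(tree, focal) {
  if (is.character(tree) && length(tree) == 1 && file.exists(tree))
    tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo or Newick path")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!focal %in% tree$tip.label) stop("focal species not a tip: ", focal)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tip_id <- match(focal, tree$tip.label)
  path <- ape::nodepath(tree, from = root, to = tip_id)
  structure(list(tree = tree, focal = focal, path = path,
                 K = length(path)), class = "fs_tree")
}

#' @export
print.fs_tree <- function(x, ...) {
  cat(sprintf("fs_tree: %d tips, focal '%s', %d age strata (1 = root)\n",
              length(x$tree$tip.label), x$focal, x$K))
  invisible(x)
}

# parent node id lookup (root maps to 0)
.parents <- function(tree) {
  p <- integer(max(tree$edge))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

#' Assign a phylostratigraphic age to one orthogroup
#'
#' The age is the node number (1 = root, K = focal tip) of the point
#' where the MRCA of the orthogroup's species attaches to the
#' root-to-focal path; an MRCA off the path is projected to its deepest
#' ancestor on the path.
#'
#' @param og_species character vector of species possessing the orthogroup;
#'   must contain the focal species.
#' @param stree an `fs_tree`.
#' @return integer age in 1..K.
#' @export
assign_gene_age <- function(og_species, stree) {
  og_species <- unique(og_species)
  if (!stree$focal %in% og_species)
    stop("orthogroup lacks the focal species; no focal-gene age defined")
  tree <- stree$tree
  missing <- setdiff(og_species, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (length(og_species) == 1L)
    return(stree$K)
  node <- ape::getMRCA(tree, og_species)
  par <- .parents(tree)
  while (!(node %in% stree$path)) node <- par[node]
  match(node, stree$path)
}

#' Assign ages for a table of orthogroups
#' @param og_table data.frame with columns `orthogroup`, `species`
#'   (long format, one row per member species).
#' @param stree an `fs_tree`.
#' @return data.frame `orthogroup`, `age`; orthogroups lacking the focal
#'   species are dropped with a message.
#' @export
assign_gene_ages <- function(og_table, stree) {
  sp <- split(og_table$species, og_table$orthogroup)
  has_focal <- vapply(sp, function(s) stree$focal %in% s, logical(1))
  if (any(!has_focal))
    message(sum(!has_focal), " orthogroup(s) without the focal species dropped")
  sp <- sp[has_focal]
  data.frame(orthogroup = names(sp),
             age = vapply(sp, assign_gene_age, integer(1), stree = stree),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcriptome age index per developmental stage
#'
#' TAI = sum_i RA_i e_i / sum_i e_i, the expression-weighted mean gene
#' age, with e_i = log2(FPKM_i + 1) by default (`log_mode = "log2p1"`);
#' `log_mode = "log2_drop"` instead uses log2(FPKM) after dropping genes
#' with FPKM < 1.  Tissue samples of a stage are first averaged per
#' replicate; TAI is computed per replicate and then averaged per stage.
#'
#' @param expr an `fs_expression` (FPKM).
#' @param ages named numeric vector or data.frame(gene, age); every
#'   expressed gene must have an age.
#' @param log_mode expression transform (see above).
#' @return list of class `fs_tai`: `by_stage` (stage, tai, n_replicates)
#'   and `by_replicate` (stage, replicate, tai).
#' @export
compute_tai <- function(expr, ages, log_mode = c("log2p1", "log2_drop")) {
  log_mode <- match.arg(log_mode)
  if (is.data.frame(ages)) ages <- setNames(ages$age, ages$gene)
  genes <- rownames(expr$values)
  expressed <- rowSums(expr$values) > 0
  noage <- genes[expressed & !(genes %in% names(ages))]
  if (length(noage))
    stop("expressed genes without an age: ", paste(head(noage), collapse = ", "))
  common <- intersect(genes, names(ages))
  v <- expr$values[common, , drop = FALSE]
  ra <- as.numeric(ages[common])
  des <- expr$design
  key <- paste(des$stage, des$replicate)
  reps <- unique(data.frame(stage = des$stage, replicate = des$replicate,
                            key = key, stringsAsFactors = FALSE))
  tai_one <- function(fpkm) {
    if (log_mode == "log2p1") {
      e <- log2(fpkm + 1)
    } else {
      keep <- fpkm >= 1
      e <- ifelse(keep, log2(pmax(fpkm, 1)), 0)
    }
    if (sum(e) == 0) return(NA_real_)
    sum(ra * e) / sum(e)
  }
  by_rep <- data.frame(stage = reps$stage, replicate = reps$replicate,
                       tai = vapply(reps$key, function(k) {
                         cols <- key == k
                         tai_one(rowMeans(v[, cols, drop = FALSE]))
                       }, numeric(1)), stringsAsFactors = FALSE,
                       row.names = NULL)
  und <- is.na(by_rep$tai)
  if (any(und))
    warning("TAI undefined (no expression) for: ",
            paste(unique(by_rep$stage[und]), collapse = ", "))
  agg <- aggregate(tai ~ stage, data = by_rep, FUN = mean, na.action = NULL)
  n <- aggregate(tai ~ stage, data = by_rep,
                 FUN = function(z) sum(!is.na(z)), na.action = NULL)
  by_stage <- data.frame(stage = agg$stage, tai = agg$tai,
                         n_replicates = n$tai, stringsAsFactors = FALSE)
  # preserve design stage order
  by_stage <- by_stage[match(unique(des$stage), by_stage$stage), , drop = FALSE]
  rownames(by_stage) <- NULL
  structure(list(by_stage = by_stage, by_replicate = by_rep),
            class = "fs_tai")
}

#' Min-max normalize ages to [0, 1]
#' @param ages numeric ages; `K` the deepest stratum count.
#' @export
normalize_ages <- function(ages, K = max(ages)) (ages - 1) / (K - 1)

#' Gene-age enrichment of a flagged gene set
#'
#' For every age stratum a 2x2 table (flagged/unflagged x in-age/other)
#' is tested with a two-sided Fisher exact test; p-values are
#' Benjamini-Hochberg corrected across strata; the sample odds ratio
#' (ad/bc) gives the direction.
#'
#' @param flags named logical vector (gene -> flagged).
#' @param ages named integer vector or data.frame(gene, age) on the same
#'   genes.
#' @return data.frame: `age`, `n_flagged`, `n_genes`, `odds_ratio`, `p`,
#'   `fdr`, `direction` ("over"/"under"/"none").
#' @export
age_enrichment <- function(flags, ages) {
  if (is.data.frame(ages)) ages <- setNames(ages$age, ages$gene)
  genes <- intersect(names(flags), names(ages))
  if (length(genes) < length(flags))
    warning(length(flags) - length(genes), " flagged gene(s) without an age ignored")
  f <- flags[genes]
  a <- ages[genes]
  strata <- sort(unique(a))
  if (length(strata) < 2) stop("need at least two distinct ages")
  res <- lapply(strata, function(s) {
    inA <- a == s
    tab <- matrix(c(sum(f & inA), sum(f & !inA),
                    sum(!f & inA), sum(!f & !inA)), 2, byrow = TRUE)
    orat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(age = s, n_flagged = tab[1, 1], n_genes = sum(inA),
               odds_ratio = orat, p = p)
  })
  res <- do.call(rbind, res)
  res$fdr <- p.adjust(res$p, method = "BH")
  res$direction <- ifelse(!is.finite(res$odds_ratio) | res$odds_ratio > 1,
                          "over", ifelse(res$odds_ratio < 1, "under", "none"))
  res$direction[res$odds_ratio == 1 | is.nan(res$odds_ratio)] <- "none"
  rownames(res) <- NULL
  res
}

# number of permutations of 1..n with k inversions, k = 0..choose(n,2);
# exact doubles up to n = 10 (10! < 2^53)
.inversion_counts <- function(n) {
  c0 <- 1
  for (m in 2:n) {
    cm <- numeric(length(c0) + m - 1)
    for (j in 0:(m - 1)) {
      idx <- seq_along(c0) + j
      cm[idx] <- cm[idx] + c0
    }
    c0 <- cm
  }
  c0
}

#' Mann-Kendall trend test
#'
#' S = sum_{i<j} sign(v_j - v_i); tau is Kendall's tau-b against the
#' index order.  For n <= 10 without ties the two-sided p-value
#' P(|S| >= |s|) is exact (inversion-number distribution over all n!
#' orderings); otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param values numeric vector in its natural (e.g. age) order, n >= 3.
#' @return list `s`, `tau`, `p`, `method`.
#' @export
mann_kendall_trend <- function(values) {
  n <- length(values)
  if (n < 3) stop("Mann-Kendall needs n >= 3")
  d <- outer(values, values, "-")
  s <- sum(sign(d[lower.tri(d)]))   # [row > col] = v_j - v_i for j > i
  n0 <- n * (n - 1) / 2
  ties <- table(values)
  ties <- ties[ties > 1]
  n1 <- sum(ties * (ties - 1) / 2)
  denom <- sqrt((n0 - n1) * n0)
  tau <- if (denom == 0) 0 else s / denom
  if (s == 0 && n1 == n0) return(list(s = 0, tau = 0, p = 1, method = "degenerate"))
  if (n <= 10 && n1 == 0) {
    counts <- .inversion_counts(n)        # S = n0 - 2k
    if (s == 0) {
      p <- 1
    } else {
      k_max <- (n0 - abs(s)) / 2          # S >= |s|  <=>  k <= k_max
      p <- 2 * sum(counts[seq_len(floor(k_max) + 1)]) / factorial(n)
      p <- min(1, p)
    }
    method <- "exact"
  } else {
    tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
    v <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
    z <- if (s == 0) 0 else (s - sign(s)) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(s = s, tau = tau, p = p, method = method)
}
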