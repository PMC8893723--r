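## Generators for every pipeline input, each with a planted ground truth,
## so downstream stages are testable without external data.  All
## generators are deterministic given their seed.

#' Default synthetic sample design
#'
#' Vegetative mycelium plus five fruiting-body stages (P1, P3, YFB, FB
#' split into cap and stipe), three biological replicates each — the
#' stage/tissue structure of a resolved mushroom developmental series.
#'
#' @param n_replicates replicates per group (default 3).
#' @return an `fs_design`.
#' @export
default_design <- function(n_replicates = 3L) {
  grp <- data.frame(stage = c("VM", "P1", "P3", "YFB", "FB", "FB"),
                    tissue = c(NA, NA, NA, NA, "C", "S"),
                    stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(grp)), each = n_replicates)
  rep_i <- rep(seq_len(n_replicates), nrow(grp))
  tis <- grp$tissue[idx]
  sample_design(
    sample_id = paste0(grp$stage[idx],
                       ifelse(is.na(tis), "", paste0("_", tis)),
                       "_R", rep_i),
    stage = grp$stage[idx], tissue = tis, replicate = rep_i,
    is_vm = grp$stage[idx] == "VM")
}

#' Simulate a stage-structured expression matrix with planted fold changes
#'
#' Baseline log2 abundances are gene-specific draws from N(4, 1.5); every
#' replicate adds lognormal noise (sd `noise_sd` on the log2 scale).  A
#' fraction `frac_dev` of genes get one uniformly chosen non-VM group
#' boosted by a fold change drawn uniformly from `fc_range`; a further
#' fraction `frac_vm_max` get the boost in VM instead (exercising the VM
#' exclusion rule; these are not counted as developmental truth).
#'
#' @param n_genes number of genes.
#' @param design an `fs_design`.
#' @param frac_dev fraction of genes with a planted developmental fold change.
#' @param fc_range length-2 numeric, planted fold-change interval (>= 1).
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param frac_vm_max fraction of genes boosted in VM instead.
#' @param seed integer seed.
#' @return list: `expr` (an `fs_expression`), `truth` (data.frame gene,
#'   is_developmental, planted_fc, planted_group, vm_max).
#' @export
gen_expression <- function(n_genes, design = default_design(),
                           frac_dev = 0.2, fc_range = c(4, 16),
                           noise_sd = 0.25, frac_vm_max = 0.05, seed = 1L) {
  if (NROW(design) == 0) stop("empty design")
  design <- validate_design(design)
  stopifnot(frac_dev >= 0, frac_dev <= 1, fc_range[1] >= 1,
            fc_range[2] >= fc_range[1], noise_sd >= 0)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  groups <- design_groups(design)
  ug <- unique(groups)
  vm_groups <- unique(groups[design$is_vm])
  nonvm <- setdiff(ug, vm_groups)
  base <- rnorm(n_genes, mean = 4, sd = 1.5)       # log2 FPKM baseline
  n_dev <- round(frac_dev * n_genes)
  n_vm <- round(frac_vm_max * n_genes)
  pick <- sample.int(n_genes, n_dev + n_vm)
  dev_idx <- pick[seq_len(n_dev)]
  vm_idx <- pick[setdiff(seq_len(n_dev + n_vm), seq_len(n_dev))]
  planted_fc <- rep(1, n_genes)
  planted_group <- rep(NA_character_, n_genes)
  if (n_dev > 0) {
    planted_fc[dev_idx] <- runif(n_dev, fc_range[1], fc_range[2])
    planted_group[dev_idx] <- sample(nonvm, n_dev, replace = TRUE)
  }
  vm_boost <- rep(1, n_genes)
  if (n_vm > 0 && length(vm_groups)) {
    vm_boost[vm_idx] <- runif(n_vm, fc_range[1], fc_range[2])
    planted_group[vm_idx] <- sample(vm_groups, n_vm, replace = TRUE)
  }
  log2mean <- matrix(base, n_genes, length(ug),
                     dimnames = list(genes, ug))
  for (i in seq_len(n_genes)) {
    g <- planted_group[i]
    if (!is.na(g))
      log2mean[i, g] <- log2mean[i, g] +
        log2(if (i %in% vm_idx) vm_boost[i] else planted_fc[i])
  }
  vals <- matrix(0, n_genes, nrow(design),
                 dimnames = list(genes, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- log2mean[, groups[j]]
    vals[, j] <- 2 ^ (mu + rnorm(n_genes, 0, noise_sd))
  }
  truth <- data.frame(gene = genes,
                      is_developmental = seq_len(n_genes) %in% dev_idx,
                      planted_fc = planted_fc,
                      planted_group = planted_group,
                      vm_max = seq_len(n_genes) %in% vm_idx,
                      stringsAsFactors = FALSE)
  list(expr = expression_matrix(vals, design), truth = truth)
}

# draw a true AS ratio for a planted class; bands leave a small margin to
# the decision boundaries so classes are identifiable at finite depth
.draw_as_ratio <- function(class, n) {
  side <- sample(c(TRUE, FALSE), n, replace = TRUE)
  p <- switch(class,
    EE = rep(0.5, n),
    S2 = runif(n, 0.69 + 1e-6, 0.80),
    S4 = runif(n, 0.80 + 1e-6, 1))
  ifelse(side, p, 1 - p)
}

#' Simulate per-gene, per-sample allele counts with planted ASE classes
#'
#' Total reads per gene/sample are Poisson(`depth_mean`); an
#' `indecisive_frac` binomial share is withheld as indecisive; decisive
#' reads are split binomially between the two nuclei at the gene's true
#' AS ratio (EE: 0.5; S2: drawn from the two-to-fourfold imbalance band;
#' S4: beyond fourfold).  The true ratio is constant across samples of a
#' gene.  A total-FPKM column is emitted as depth/10 so default masking
#' thresholds behave as on real data.
#'
#' @param n_genes number of genes.
#' @param design an `fs_design`.
#' @param class_mix named proportions over EE/S2/S4 (default .7/.15/.15).
#' @param depth_mean mean total reads per gene and sample.
#' @param indecisive_frac expected indecisive read fraction.
#' @param seed integer seed.
#' @return list: `counts` (data.frame gene, sample, count_a, count_b,
#'   count_indecisive, fpkm_total), `truth` (gene, true_class,
#'   true_as_ratio).
#' @export
gen_allele_counts <- function(n_genes, design = default_design(),
                              class_mix = c(EE = 0.7, S2 = 0.15, S4 = 0.15),
                              depth_mean = 200, indecisive_frac = 0.2,
                              seed = 1L) {
  design <- validate_design(design)
  if (depth_mean <= 0) stop("depth_mean must be positive")
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% c("EE", "S2", "S4")))
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  cls <- sample(names(class_mix), n_genes, replace = TRUE, prob = class_mix)
  ratio <- numeric(n_genes)
  for (k in unique(cls))
    ratio[cls == k] <- .draw_as_ratio(k, sum(cls == k))
  ns <- nrow(design)
  total <- matrix(rpois(n_genes * ns, depth_mean), n_genes, ns)
  ind <- matrix(rbinom(n_genes * ns, total, indecisive_frac), n_genes, ns)
  dec <- total - ind
  a <- matrix(rbinom(n_genes * ns, dec, rep(ratio, ns)), n_genes, ns)
  counts <- data.frame(
    gene = rep(genes, ns),
    sample = rep(design$sample_id, each = n_genes),
    count_a = as.vector(a),
    count_b = as.vector(dec - a),
    count_indecisive = as.vector(ind),
    fpkm_total = as.vector(total) / 10,
    stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, true_class = cls, true_as_ratio = ratio,
                      stringsAsFactors = FALSE)
  list(counts = allele_count_table(counts), truth = truth)
}

#' Simulate reads over SNP haplotypes with sequencing error
#'
#' Each read starts at a uniformly chosen variant site and observes every
#' variant within `read_len` bases downstream on the same contig.  The
#' read's nucleus of origin is parent A with probability `parent_mix`;
#' each observed base is flipped to a uniformly chosen other base
#' independently with probability `error_rate`.  Phred scores are set to
#' 40 (the generator models base-call errors, not quality).
#'
#' @param variants an `fs_variants` table.
#' @param read_len read length in nt.
#' @param n_reads number of reads.
#' @param error_rate per-base error probability (<= 0.1).
#' @param parent_mix probability a read originates from parent A.
#' @param seed integer seed.
#' @return list: `obs` (data.frame read_id, contig, position, base,
#'   phred), `truth` (read_id, true_parent, n_sites).
#' @export
gen_reads <- function(variants, read_len = 150L, n_reads = 1000L,
                      error_rate = 0.01, parent_mix = 0.5, seed = 1L) {
  stopifnot(read_len >= 1, error_rate >= 0, error_rate <= 0.1,
            parent_mix >= 0, parent_mix <= 1)
  if (nrow(variants) == 0) stop("no variants to place reads on")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  start_i <- sample.int(nrow(variants), n_reads, replace = TRUE)
  from_a <- runif(n_reads) < parent_mix
  obs <- vector("list", n_reads)
  n_sites <- integer(n_reads)
  for (r in seq_len(n_reads)) {
    i <- start_i[r]
    ctg <- variants$contig[i]
    p0 <- variants$position[i]
    cov <- which(variants$contig == ctg &
                 variants$position >= p0 &
                 variants$position < p0 + read_len)
    n_sites[r] <- length(cov)
    true_base <- if (from_a[r]) variants$allele_a[cov] else variants$allele_b[cov]
    err <- runif(length(cov)) < error_rate
    seen <- true_base
    if (any(err))
      seen[err] <- vapply(true_base[err], function(b)
        sample(setdiff(bases, b), 1L), "")
    obs[[r]] <- data.frame(read_id = sprintf("r%06d", r), contig = ctg,
                           position = variants$position[cov], base = seen,
                           phred = 40L, stringsAsFactors = FALSE)
  }
  truth <- data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
                      true_parent = ifelse(from_a, "A", "B"),
                      n_sites = n_sites, stringsAsFactors = FALSE)
  if (any(n_sites == 0))
    warning(sum(n_sites == 0), " read(s) cover zero informative sites")
  list(obs = do.call(rbind, obs), truth = truth)
}

#' Simulate orthogroup presence/absence by gene birth with stochastic loss
#'
#' Each orthogroup is born on a uniformly chosen node (or tip) of the
#' species tree and inherited by all descendant species, except
#' independent losses with probability `loss_prob` per non-focal species.
#' Orthogroups that would lose the focal species are redrawn, so every
#' group carries a focal gene.  The recorded true age is the birth
#' node's projection onto the numbered root-to-focal path — exactly the
#' value age assignment recovers when no loss occurs.
#'
#' @param stree an `fs_tree`.
#' @param n_groups number of orthogroups.
#' @param loss_prob per-species loss probability in [0, 1).
#' @param seed integer seed.
#' @return list: `og_table` (long data.frame orthogroup, species),
#'   `truth` (orthogroup, true_age, birth_node).
#' @export
gen_orthogroups <- function(stree, n_groups, loss_prob = 0.1, seed = 1L) {
  if (loss_prob >= 1 || loss_prob < 0) stop("loss_prob must be in [0, 1)")
  tree <- stree$tree
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree needs at least 2 tips")
  set.seed(seed)
  par <- .parents(tree)
  n_nodes <- ntip + tree$Nnode
  # descendant tips and on-path projection per node
  desc <- vector("list", n_nodes)
  proj <- integer(n_nodes)
  for (nd in seq_len(n_nodes)) {
    desc[[nd]] <- tree$tip.label[.descend_tips(tree, nd)]
    p <- nd
    while (!(p %in% stree$path)) p <- par[p]
    proj[nd] <- match(p, stree$path)
  }
  # nodes whose clade contains the focal species can always yield a
  # focal-bearing group; others never can — restrict the draw
  has_focal <- vapply(desc, function(s) stree$focal %in% s, logical(1))
  cand <- which(has_focal)
  og <- vector("list", n_groups)
  truth <- data.frame(orthogroup = sprintf("OG%05d", seq_len(n_groups)),
                      true_age = NA_integer_, birth_node = NA_integer_)
  for (g in seq_len(n_groups)) {
    repeat {
      birth <- cand[sample.int(length(cand), 1L)]
      sp <- desc[[birth]]
      keep <- sp == stree$focal | runif(length(sp)) >= loss_prob
      sp <- sp[keep]
      if (stree$focal %in% sp) break
    }
    og[[g]] <- data.frame(orthogroup = truth$orthogroup[g], species = sp,
                          stringsAsFactors = FALSE)
    truth$true_age[g] <- proj[birth]
    truth$birth_node[g] <- birth
  }
  list(og_table = do.call(rbind, og), truth = truth)
}

# logical vector over tips: is tip a descendant of node `nd`
.descend_tips <- function(tree, nd) {
  ntip <- length(tree$tip.label)
  if (nd <= ntip) {
    out <- rep(FALSE, ntip); out[nd] <- TRUE; return(out)
  }
  kids <- tree$edge[tree$edge[, 1] == nd, 2]
  Reduce(`|`, lapply(kids, .descend_tips, tree = tree))
}
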