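## Classification of developmentally expressed genes from stage-structured
## FPKM tables.  A gene is developmental at threshold t when its expression
## changes at least t-fold between some two non-VM sample groups, its peak
## group mean exceeds an FPKM floor, and the global peak is not in
## vegetative mycelium.

#' Compute FPKM from raw counts
#'
#' FPKM = count * 1e9 / (gene length * library size).
#'
#' @param counts integer gene x sample matrix.
#' @param gene_lengths positive transcript lengths (nt), one per gene.
#' @param library_sizes positive mapped-fragment totals, one per sample.
#' @param design an `fs_design` for the columns.
#' @return an `fs_expression` of FPKM values.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes, design) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths length must match rows")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes length must match columns")
  if (any(gene_lengths <= 0))
    stop("non-positive gene length for: ",
         paste(head(rownames(counts)[gene_lengths <= 0]), collapse = ", "))
  if (any(library_sizes <= 0)) stop("non-positive library size")
  fpkm <- counts * 1e9 / outer(as.numeric(gene_lengths),
                               as.numeric(library_sizes))
  expression_matrix(fpkm, design)
}

#' Per-group replicate means
#'
#' @param expr an `fs_expression`.
#' @return list with `means` (gene x group matrix), `is_vm` (logical per
#'   group), `groups` (group labels).
#' @export
group_means <- function(expr) {
  g <- design_groups(expr$design)
  ug <- unique(g)
  m <- vapply(ug, function(k)
    rowMeans(expr$values[, g == k, drop = FALSE]), numeric(nrow(expr$values)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(rownames(expr$values), ug))
  vm <- vapply(ug, function(k) any(expr$design$is_vm[g == k]), logical(1))
  list(means = m, is_vm = vm, groups = ug)
}

#' Classify developmentally expressed genes
#'
#' Replicate means are computed per (stage, tissue) group.  `max_fc` is
#' the largest larger/smaller ratio of group means over all pairs of
#' non-VM groups, with means floored at `fc_floor` FPKM so that on/off
#' genes yield finite fold changes.  A gene is developmental at threshold
#' `fc_threshold` when `max_fc >= fc_threshold`, its maximal group mean
#' exceeds `min_fpkm`, and the globally maximal group (VM included) is
#' not VM; genes peaking in VM are flagged `excluded_vm`.
#'
#' @param expr an `fs_expression` (FPKM).
#' @param fc_threshold fold-change threshold (published analyses use 2 and 4).
#' @param min_fpkm minimum peak group-mean FPKM (default 4).
#' @param fc_floor pseudo-floor applied to group means in ratios (default 0.1).
#' @return data.frame with one row per gene: `gene`, `max_fc`, `max_group`
#'   (non-VM peak group), `is_dev_fc2`, `is_dev_fc4`, `is_dev` (at
#'   `fc_threshold`), `excluded_vm`.
#' @export
classify_developmental <- function(expr, fc_threshold = 4, min_fpkm = 4,
                                   fc_floor = 0.1) {
  gm <- group_means(expr)
  nonvm <- !gm$is_vm
  if (sum(nonvm) < 2)
    stop("need at least two non-VM sample groups for fold changes")
  m <- gm$means[, nonvm, drop = FALSE]
  mf <- pmax(m, fc_floor)
  hi <- apply(mf, 1, max)
  lo <- apply(mf, 1, min)
  max_fc <- hi / lo
  peak <- colnames(m)[max.col(m, ties.method = "first")]
  peak_mean <- apply(m, 1, max)
  # global peak across all groups, VM included
  vm_max <- if (any(gm$is_vm)) {
    vmm <- apply(gm$means[, gm$is_vm, drop = FALSE], 1, max)
    vmm > peak_mean
  } else rep(FALSE, nrow(m))
  dev_at <- function(t) max_fc >= t & peak_mean > min_fpkm & !vm_max
  res <- data.frame(gene = rownames(gm$means),
                    max_fc = unname(max_fc),
                    max_group = unname(peak),
                    is_dev_fc2 = unname(dev_at(2)),
                    is_dev_fc4 = unname(dev_at(4)),
                    is_dev = unname(dev_at(fc_threshold)),
                    excluded_vm = unname(vm_max),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
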