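# Shared fixtures, built in code.

fix_tree7 <- function() {
  nwk <- "(((((F:1,E:1):1,D:1):1,C:1):1,B:1):1,A:2);"
  species_tree(ape::read.tree(text = nwk), "F")
}

fix_design <- function(n_replicates = 3L) default_design(n_replicates)

# tiny deterministic expression fixture: 3 groups (VM, P1, FB), 2 reps
fix_small_expr <- function(means, noise = 0) {
  design <- sample_design(
    sample_id = c("VM_1", "VM_2", "P1_1", "P1_2", "FB_1", "FB_2"),
    stage = rep(c("VM", "P1", "FB"), each = 2),
    replicate = rep(1:2, 3),
    is_vm = rep(c(TRUE, FALSE, FALSE), each = 2))
  m <- means[, rep(1:3, each = 2), drop = FALSE]
  dimnames(m) <- list(rownames(means), design$sample_id)
  if (noise > 0) m <- m * 2 ^ matrix(rnorm(length(m), 0, noise), nrow(m))
  expression_matrix(m, design)
}

# means: gene x 3 matrix (VM, P1, FB) replicated over 2 samples each
fix_expr_from_means <- function(means) {
  rownames(means) <- rownames(means) %||% paste0("g", seq_len(nrow(means)))
  fix_small_expr(means)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
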