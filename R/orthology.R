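## Orthology from all-vs-all protein hits: asymmetric coverage
## filtering, Markov clustering of the Nident/qlen-weighted family
## graph, single-copy orthogroups from reciprocal best hits with a
## spurious-member filter, conserved-orthogroup classification, and the
## shared vs complex-multicellularity-specific split against the
## simple-development outgroup.

#' Asymmetric coverage filter for protein hits
#'
#' A hit is retained when the alignment covers at least `long_cov` of
#' the longer protein and at least `short_cov` of the shorter one —
#' discarding aspecific hits while keeping gene fragments.
#'
#' @param hits an `fs_hits` table.
#' @param long_cov,short_cov coverage floors (defaults 0.2 and 0.8).
#' @return filtered `fs_hits`.
#' @export
coverage_filter <- function(hits, long_cov = 0.2, short_cov = 0.8) {
  hits <- hit_table(hits)
  q_longer <- hits$qlen >= hits$slen
  cov_long <- ifelse(q_longer, hits$qcov, hits$scov)
  cov_short <- ifelse(q_longer, hits$scov, hits$qcov)
  out <- hits[cov_long >= long_cov & cov_short >= short_cov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the protein family graph weighted by Nident/qlen
#'
#' @param hits an `fs_hits` table (coverage-filtered).
#' @return list: `vertices`, symmetric weight `matrix` (max of the two
#'   directed Nident/qlen weights; self-hits ignored).
#' @export
family_graph <- function(hits) {
  v <- sort(unique(c(hits$query, hits$target)))
  w <- matrix(0, length(v), length(v), dimnames = list(v, v))
  qi <- match(hits$query, v); ti <- match(hits$target, v)
  wt <- pmin(1, hits$nident / hits$qlen)
  keep <- qi != ti
  for (k in which(keep)) {
    i <- qi[k]; j <- ti[k]
    w[i, j] <- max(w[i, j], wt[k])
  }
  w <- pmax(w, t(w))
  list(vertices = v, matrix = w)
}

# connected-component labels of a symmetric adjacency (nonzero = edge)
.components <- function(adj) {
  n <- nrow(adj)
  lab <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[u]) next
      lab[u] <- cur
      nb <- which(adj[u, ] != 0 & lab == 0L)
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Markov clustering (MCL)
#'
#' Standard MCL on a symmetric weighted graph: self-loops are added with
#' each vertex's maximum incident edge weight, columns are normalized to
#' stochastic, then expansion (matrix squaring) and inflation
#' (elementwise power `inflation`, renormalize) alternate, pruning
#' entries below `prune`, until the matrix changes by less than `tol` or
#' `max_iter` is reached (then the current partition is returned with a
#' warning).  Clusters are the connected components of the converged
#' matrix's nonzero pattern; output clusters are ordered, and vertices
#' within clusters sorted, lexicographically, so the result is
#' deterministic regardless of input order.
#'
#' @param graph output of [family_graph()] or a symmetric numeric matrix
#'   with dimnames.
#' @param inflation inflation parameter (> 1; default 2.0).
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter iteration cap.
#' @param prune entries below this are zeroed each iteration.
#' @return list of character vectors (the clusters).
#' @export
mcl_cluster <- function(graph, inflation = 2.0, tol = 1e-6,
                        max_iter = 100L, prune = 1e-8) {
  w <- if (is.list(graph)) graph$matrix else as.matrix(graph)
  if (nrow(w) == 0) stop("empty graph")
  if (is.null(rownames(w))) stop("graph matrix needs dimnames")
  stopifnot(inflation > 1)
  n <- nrow(w)
  loops <- apply(w, 1, max)
  loops[loops == 0] <- 1            # isolated vertices keep themselves
  diag(w) <- loops
  norm_cols <- function(m) sweep(m, 2, colSums(m), "/")
  m <- norm_cols(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m                    # expansion
    m2 <- m2 ^ inflation             # inflation
    m2[m2 < prune] <- 0
    m2 <- norm_cols(m2)
    if (max(abs(m2 - m)) < tol) { m <- m2; converged <- TRUE; break }
    m <- m2
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations")
  adj <- (m > prune) | (t(m) > prune)
  lab <- .components(adj)
  cl <- split(rownames(w), lab)
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[[`, "", 1L))]
}

# order hits best-first: bitscore desc, evalue asc, target label asc
.best_order <- function(h) order(-h$bitscore, h$evalue, h$target)

#' Single-copy orthogroups from reciprocal best hits
#'
#' Hits are thresholded at `evalue_cutoff`; for every protein its best
#' cross-species hit per target species is found (ties broken by higher
#' bitscore, then lower e-value, then lexicographic label).  Proteins p,
#' q are reciprocal best hits when each is the other's best in its
#' species.  Groups are assembled around each seed-species protein from
#' its RBH partners, at most one per species; each member carries its
#' bitscore to the seed and, when the hit table allows, the fraction of
#' its hit targets shared with the seed's.
#'
#' @param hits an `fs_hits` table pooled over species pairs (both
#'   directions).
#' @param species named character vector protein -> species.
#' @param seed_species species whose proteins seed the groups.
#' @param evalue_cutoff e-value threshold (default 1e-5).
#' @return data.frame: group (seed protein), member, species, bitscore,
#'   hit_overlap.
#' @export
build_rbh_groups <- function(hits, species, seed_species,
                             evalue_cutoff = 1e-5) {
  hits <- hit_table(hits)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  sp_q <- species[hits$query]; sp_t <- species[hits$target]
  if (anyNA(sp_q) || anyNA(sp_t))
    stop("proteins missing from the species map")
  cross <- sp_q != sp_t
  h <- hits[cross, , drop = FALSE]
  h <- h[.best_order(h), , drop = FALSE]
  # best hit per (query, target-species): first after sorting
  key <- paste(h$query, species[h$target])
  best <- h[!duplicated(key), , drop = FALSE]
  bkey <- paste(best$query, best$target)
  is_best <- function(q, t) paste(q, t) %in% bkey
  # hit-target sets for overlap computation
  tg <- split(hits$target, hits$query)
  overlap <- function(a, b) {
    ha <- unique(tg[[a]]); hb <- unique(tg[[b]])
    if (is.null(ha) || !length(ha)) return(NA_real_)
    length(intersect(ha, hb)) / length(ha)
  }
  seeds <- sort(unique(names(species)[species == seed_species]))
  rows <- list()
  for (s in seeds) {
    mine <- best[best$query == s, , drop = FALSE]
    members <- data.frame(group = s, member = s, species = seed_species,
                          bitscore = NA_real_, hit_overlap = 1,
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mine))) {
      q <- mine$target[i]
      if (is_best(q, s))              # reciprocity
        members <- rbind(members,
          data.frame(group = s, member = q, species = species[[q]],
                     bitscore = mine$bitscore[i],
                     hit_overlap = overlap(q, s),
                     stringsAsFactors = FALSE))
    }
    if (nrow(members) > 1) rows[[s]] <- members
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), member = character(),
                      species = character(), bitscore = numeric(),
                      hit_overlap = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove spurious members from an RBH group
#'
#' A member is dropped when its bitscore to the seed is at least
#' `bitscore_factor` times lower than the mean bitscore of the other
#' members (self excluded) AND it shares less than `max_overlap` of its
#' hits with the seed's hits.  The test is iterated to a fixed point,
#' recomputing means after each removal; the seed itself is never
#' removed.  Groups with fewer than three scored members are returned
#' unchanged.
#'
#' @param group one group's rows from [build_rbh_groups()].
#' @param bitscore_factor default 3.
#' @param max_overlap default 0.5.
#' @return the filtered group.
#' @export
filter_spurious_members <- function(group, bitscore_factor = 3,
                                    max_overlap = 0.5) {
  repeat {
    scored <- which(!is.na(group$bitscore))
    if (length(scored) < 2) return(group)   # 2-member group: mean of others undefined
    drop <- NULL
    for (i in scored) {
      others <- setdiff(scored, i)
      mb <- mean(group$bitscore[others])
      if (group$bitscore[i] < mb / bitscore_factor &&
          !is.na(group$hit_overlap[i]) &&
          group$hit_overlap[i] < max_overlap) { drop <- c(drop, i) }
    }
    if (is.null(drop)) return(group)
    # remove the worst offender only, then re-evaluate
    worst <- drop[which.min(group$bitscore[drop])]
    group <- group[-worst, , drop = FALSE]
  }
}

#' Classify conserved developmental orthogroups
#'
#' An orthogroup is conserved when it is developmentally expressed (at
#' FC > 2, per species) in at least `min_species` species and the
#' developmental share reaches `min_prop` — with the share's denominator
#' either the species possessing the orthogroup (default) or all
#' surveyed species.
#'
#' @param og_dev data.frame: orthogroup, species, present (logical),
#'   is_dev (logical; NA where absent).
#' @param min_species default 4.
#' @param min_prop default 0.5.
#' @param denominator "present" or "all".
#' @param n_all total species count (needed for `denominator = "all"`;
#'   defaults to the number of distinct species in `og_dev`).
#' @return data.frame: orthogroup, n_present, n_dev, dev_proportion,
#'   conserved.
#' @export
classify_conserved <- function(og_dev, min_species = 4L, min_prop = 0.5,
                               denominator = c("present", "all"),
                               n_all = length(unique(og_dev$species))) {
  denominator <- match.arg(denominator)
  sp <- split(og_dev, og_dev$orthogroup)
  res <- lapply(sp, function(d) {
    np <- sum(d$present)
    if (np == 0) stop("orthogroup present nowhere: ", d$orthogroup[1])
    nd <- sum(d$present & d$is_dev, na.rm = TRUE)
    den <- if (denominator == "present") np else n_all
    data.frame(orthogroup = d$orthogroup[1], n_present = np, n_dev = nd,
               dev_proportion = nd / den,
               conserved = nd >= min_species & nd / den >= min_prop,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Split conserved orthogroups into shared and CM-specific sets
#'
#' A conserved orthogroup is `shared` when its ortholog in the
#' simple-development outgroup is developmentally expressed (FC > 2),
#' `cm_missing` when the outgroup ortholog is absent, and `cm_nondev`
#' when present but not developmentally regulated.  Non-conserved
#' orthogroups are passed through as `nonconserved`.
#'
#' @param conserved output of [classify_conserved()].
#' @param outgroup_status named vector orthogroup -> "dev"/"nondev"/
#'   "absent".
#' @return input with a `category` column.
#' @export
split_shared_cm <- function(conserved, outgroup_status) {
  st <- outgroup_status[conserved$orthogroup]
  if (anyNA(st))
    stop("outgroup status missing for: ",
         paste(head(conserved$orthogroup[is.na(st)]), collapse = ", "))
  conserved$category <- ifelse(!conserved$conserved, "nonconserved",
                        ifelse(st == "dev", "shared",
                        ifelse(st == "absent", "cm_missing", "cm_nondev")))
  conserved
}

#' Age enrichment of an orthogroup category
#'
#' Fisher/BH enrichment of a category against all orthogroups per age
#' stratum; shares the [age_enrichment()] code path.
#'
#' @param classes output of [split_shared_cm()].
#' @param ages named vector orthogroup -> age.
#' @param category category to test (default "cm_missing" +
#'   "cm_nondev", i.e. CM-specific).
#' @return see [age_enrichment()].
#' @export
og_origin_enrichment <- function(classes, ages,
                                 category = c("cm_missing", "cm_nondev")) {
  flags <- setNames(classes$category %in% category, classes$orthogroup)
  age_enrichment(flags, ages)
}

#' Percent identity of two upstream regions by global alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' linear gap -2 by default; identity = matches / alignment columns x
#' 100.  Intended for the region from 1000 nt upstream to 200 nt
#' downstream of the transcription start of the two parental alleles.
#'
#' @param seq_a,seq_b nucleotide strings (ACGTN).
#' @param match,mismatch,gap scoring (defaults +1/-1/-2).
#' @return percent identity in [0, 100].
#' @export
upstream_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap = -2) {
  chk <- function(s) {
    if (!nzchar(s)) stop("empty sequence")
    if (grepl("[^ACGTNacgtn]", s)) stop("non-ACGTN character in sequence")
    toupper(s)
  }
  seq_a <- chk(seq_a); seq_b <- chk(seq_b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0,
                                       gapExtension = abs(gap))
  pa <- as.character(Biostrings::alignedPattern(aln))
  ps <- as.character(Biostrings::alignedSubject(aln))
  a <- strsplit(pa, "")[[1]]
  b <- strsplit(ps, "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}
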