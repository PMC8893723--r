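## First stage of the mismatch pipeline: each observed read base at a
## known site is partitioned into quality-discarded, allele marker
## (feeds ASE), editing/technical candidate (feeds the RNA-editing
## filters), or plain match.

#' Classify a read-base observation at a site
#'
#' Rules, in order: a base below the Phred floor (or an N) is
#' `discarded_quality`; a base differing the same way from both parental
#' alleles (the parents agree, the read disagrees) is `both_diff` — an
#' RNA-editing / technical-error candidate; where the parents differ, a
#' base matching exactly one parent is an `allele_marker`, and a base
#' matching neither is `both_diff` flagged `third_allele`; anything else
#' is `match`.
#'
#' @param base,allele_a,allele_b observed and parental bases (vectors).
#' @param phred per-observation quality.
#' @param min_phred Phred floor (default 30).
#' @return data.frame: class ("match"/"allele_marker"/"both_diff"/
#'   "discarded_quality"), matched_parent ("A"/"B"/NA),
#'   third_allele (logical).
#' @export
classify_site <- function(base, allele_a, allele_b, phred,
                          min_phred = 30L) {
  base <- toupper(base); allele_a <- toupper(allele_a)
  allele_b <- toupper(allele_b)
  n <- length(base)
  stopifnot(length(allele_a) == n, length(allele_b) == n,
            length(phred) == n)
  cls <- rep("match", n)
  parent <- rep(NA_character_, n)
  third <- rep(FALSE, n)
  low <- phred < min_phred | base == "N"
  same <- allele_a == allele_b
  eq_a <- base == allele_a
  eq_b <- base == allele_b
  # parents agree, read disagrees: candidate
  cand <- !low & same & !eq_a
  cls[cand] <- "both_diff"
  # parents differ
  mk_a <- !low & !same & eq_a
  mk_b <- !low & !same & eq_b
  cls[mk_a | mk_b] <- "allele_marker"
  parent[mk_a] <- "A"; parent[mk_b] <- "B"
  thr <- !low & !same & !eq_a & !eq_b
  cls[thr] <- "both_diff"
  third[thr] <- TRUE
  cls[low] <- "discarded_quality"
  data.frame(class = cls, matched_parent = parent, third_allele = third,
             stringsAsFactors = FALSE)
}

#' Summarize RNA-editing candidate sites
#'
#' Aggregates `both_diff` observations per site into variant read
#' support (VRS), total read support (RS, all quality-passing
#' observations at the site) and relative variant frequency
#' (RVF = VRS/RS); retains sites passing all three thresholds and scores
#' each for A-to-I compatibility (A->G on a plus-strand transcript,
#' T->C on minus strand).  The threshold defaults are artifact choices,
#' not published values; set them in the configuration.
#'
#' @param obs data.frame with contig, position, base, phred, allele_a,
#'   allele_b and (optionally) precomputed classes.
#' @param strand named character vector contig:position -> "+"/"-" or a
#'   data.frame (contig, position, strand); missing sites get NA
#'   compatibility.
#' @param min_vrs,min_rs,min_rvf retention thresholds (defaults 3, 10, 0.1).
#' @param min_phred Phred floor for RS (default 30).
#' @return list: `sites` (contig, position, ref, var, vrs, rs, rvf,
#'   strand, is_ag_compatible), `ag_fraction` (share of A-to-I-compatible
#'   sites among retained; NA if none retained).
#' @export
summarize_editing <- function(obs, strand = NULL, min_vrs = 3L,
                              min_rs = 10L, min_rvf = 0.1,
                              min_phred = 30L) {
  cl <- classify_site(obs$base, obs$allele_a, obs$allele_b, obs$phred,
                      min_phred = min_phred)
  ok <- cl$class != "discarded_quality"
  key <- paste(obs$contig, obs$position)
  rs <- tapply(ok, key, sum)
  cand <- cl$class == "both_diff"
  if (!any(cand)) {
    return(list(sites = data.frame(contig = character(), position = integer(),
                                   ref = character(), var = character(),
                                   vrs = integer(), rs = integer(),
                                   rvf = numeric(), strand = character(),
                                   is_ag_compatible = logical()),
                ag_fraction = NA_real_))
  }
  co <- obs[cand, , drop = FALSE]
  ckey <- paste(co$contig, co$position)
  agg <- lapply(split(seq_len(nrow(co)), ckey), function(i) {
    tb <- sort(table(co$base[i]), decreasing = TRUE)
    data.frame(contig = co$contig[i[1]], position = co$position[i[1]],
               ref = co$allele_a[i[1]], var = names(tb)[1],
               vrs = as.integer(tb[1]), stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, agg)
  sites$rs <- as.integer(rs[paste(sites$contig, sites$position)])
  sites$rvf <- sites$vrs / sites$rs
  keep <- sites$vrs >= min_vrs & sites$rs >= min_rs & sites$rvf >= min_rvf
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0) {
    sites$strand <- character(0)
    sites$is_ag_compatible <- logical(0)
    return(list(sites = sites, ag_fraction = NA_real_))
  }
  if (is.data.frame(strand))
    strand <- setNames(strand$strand, paste(strand$contig, strand$position))
  sites$strand <- if (is.null(strand)) NA_character_
                  else unname(strand[paste(sites$contig, sites$position)])
  sites$is_ag_compatible <- ifelse(
    is.na(sites$strand), NA,
    (sites$strand == "+" & sites$ref == "A" & sites$var == "G") |
    (sites$strand == "-" & sites$ref == "T" & sites$var == "C"))
  rownames(sites) <- NULL
  ag <- if (nrow(sites) == 0 || all(is.na(sites$is_ag_compatible)))
    NA_real_
  else mean(sites$is_ag_compatible, na.rm = TRUE)
  list(sites = sites, ag_fraction = ag)
}
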