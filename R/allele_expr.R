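## Allele-specific expression between the two parental nuclei of a
## dikaryon: Hamming-distance read assignment, AS ratios with masking,
## EE/S2/S4 classification on replicate geometric means, and
## chromosome/nucleus read ratios.

#' Validate an allele count table
#' @param tab data.frame with columns gene, sample, count_a, count_b,
#'   count_indecisive, fpkm_total.
#' @return `fs_allele_counts` data.frame.
#' @export
allele_count_table <- function(tab) {
  need <- c("gene", "sample", "count_a", "count_b", "count_indecisive",
            "fpkm_total")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("allele count table lacks columns: ", paste(miss, collapse = ", "))
  if (any(tab$count_a < 0 | tab$count_b < 0 | tab$count_indecisive < 0))
    stop("negative read counts")
  if (anyDuplicated(paste(tab$gene, tab$sample)))
    stop("duplicate (gene, sample) rows")
  class(tab) <- c("fs_allele_counts", "data.frame")
  tab
}

#' Assign reads to a parental nucleus by Hamming distance
#'
#' Each read's Hamming distances to the two parental haplotypes are the
#' mismatch counts over the SNPs it covers (Hd = number of SNPs).  The
#' read is assigned to the parent with the smaller Hd, and called
#' indecisive when (i) Hd > 1 from both genomes, (ii) Hd > 15 from any
#' genome (too-divergent read; `divergent_rule = "closer"` instead
#' applies the cutoff only to the closer genome), or (iii) the distances
#' are tied.  Reads covering no SNP are tied at 0 and hence indecisive.
#'
#' @param hd_a,hd_b integer vectors of per-read distances.
#' @param max_hd_decisive rule (i) cutoff (default 1).
#' @param max_hd_divergent rule (ii) cutoff (default 15).
#' @param divergent_rule "any" (literal) or "closer".
#' @return data.frame: `hd_a`, `hd_b`, `call` ("parentA"/"parentB"/
#'   "indecisive"), `reason` ("none"/"both_gt1"/"too_divergent"/"tie").
#' @export
assign_read <- function(hd_a, hd_b, max_hd_decisive = 1L,
                        max_hd_divergent = 15L,
                        divergent_rule = c("any", "closer")) {
  divergent_rule <- match.arg(divergent_rule)
  stopifnot(length(hd_a) == length(hd_b), all(hd_a >= 0), all(hd_b >= 0))
  both_far <- hd_a > max_hd_decisive & hd_b > max_hd_decisive
  div <- if (divergent_rule == "any")
    pmax(hd_a, hd_b) > max_hd_divergent
  else
    pmin(hd_a, hd_b) > max_hd_divergent
  tie <- hd_a == hd_b
  reason <- rep("none", length(hd_a))
  reason[tie] <- "tie"
  reason[div] <- "too_divergent"
  reason[both_far] <- "both_gt1"
  call <- ifelse(reason != "none", "indecisive",
                 ifelse(hd_a < hd_b, "parentA", "parentB"))
  data.frame(hd_a = hd_a, hd_b = hd_b, call = call, reason = reason,
             stringsAsFactors = FALSE)
}

#' Hamming distances and assignment for a per-read SNP observation table
#'
#' @param obs data.frame (read_id, contig, position, base, phred); bases
#'   below `min_phred` are ignored (they were discarded upstream in the
#'   variant-partition stage).
#' @param variants an `fs_variants` table.
#' @param ... passed to [assign_read()].
#' @param min_phred Phred floor (default 30).
#' @return data.frame: read_id, n_sites, hd_a, hd_b, call, reason.
#' @export
assign_reads_from_obs <- function(obs, variants, min_phred = 30L, ...) {
  key <- paste(obs$contig, obs$position)
  vkey <- paste(variants$contig, variants$position)
  idx <- match(key, vkey)
  known <- !is.na(idx) & obs$phred >= min_phred
  mm_a <- known & obs$base != variants$allele_a[idx]
  mm_b <- known & obs$base != variants$allele_b[idx]
  reads <- unique(obs$read_id)
  f <- factor(obs$read_id, levels = reads)
  hd_a <- as.integer(tapply(mm_a, f, sum, default = 0L))
  hd_b <- as.integer(tapply(mm_b, f, sum, default = 0L))
  n_sites <- as.integer(tapply(known, f, sum, default = 0L))
  out <- assign_read(hd_a, hd_b, ...)
  cbind(data.frame(read_id = reads, n_sites = n_sites,
                   stringsAsFactors = FALSE), out)
}

#' AS ratios with masking
#'
#' AS = count_a / (count_a + count_b), the share of reads from nucleus A
#' among decisively assigned reads.  The ratio is masked to 0.5 when the
#' gene's expression is too low (`fpkm_total < min_fpkm`), decisive reads
#' are fewer than `min_decisive`, or the indecisive read share exceeds
#' `max_indecisive_frac`.
#'
#' @param counts an `fs_allele_counts` table.
#' @param min_fpkm FPKM floor (default 2).
#' @param min_decisive minimum decisive reads (default 16).
#' @param max_indecisive_frac maximum indecisive share (default 0.8).
#' @return data.frame: gene, sample, as, masked, mask_reason
#'   ("low_fpkm"/"few_decisive"/"indecisive_dominant"/"none").
#' @export
compute_as_ratio <- function(counts, min_fpkm = 2, min_decisive = 16L,
                             max_indecisive_frac = 0.8) {
  counts <- allele_count_table(counts)
  dec <- counts$count_a + counts$count_b
  tot <- dec + counts$count_indecisive
  ind_frac <- ifelse(tot > 0, counts$count_indecisive / tot, 1)
  reason <- rep("none", nrow(counts))
  reason[ind_frac > max_indecisive_frac] <- "indecisive_dominant"
  reason[dec < min_decisive] <- "few_decisive"
  reason[counts$fpkm_total < min_fpkm] <- "low_fpkm"
  masked <- reason != "none"
  as_val <- ifelse(masked | dec == 0, 0.5, counts$count_a / dec)
  data.frame(gene = counts$gene, sample = counts$sample, as = as_val,
             masked = masked, mask_reason = reason, stringsAsFactors = FALSE)
}

# geometric mean
.gm <- function(x) exp(mean(log(x)))

#' Classify genes as EE / S2 / S4 from AS ratios
#'
#' A gene is allele-specifically expressed when, in at least one
#' (stage, tissue) group, every unmasked replicate is biased toward the
#' same nucleus (strictly on one side of 0.5; masked replicates count as
#' unbiased and break the group) and the geometric mean of the replicate
#' AS ratios crosses the class band: > `s4_band[2]` (or, mirrored,
#' the geometric mean of 1 - AS for nucleus-B bias, i.e. AS <
#' `s4_band[1]`) for S4, and likewise with `s2_band` for S2.  S4 takes
#' precedence; genes qualifying in no group are EE.  With
#' `gm_mode = "direct"` the nucleus-B test compares the geometric mean
#' of AS itself against the lower limit.
#'
#' @param as_tab output of [compute_as_ratio()].
#' @param design an `fs_design` mapping samples to groups/replicates.
#' @param s2_band,s4_band lower/upper AS cutoffs (defaults c(0.31, 0.68)
#'   and c(0.2, 0.8), the published two- and fourfold bands).
#' @param gm_mode "mirrored" (default) or "direct".
#' @return data.frame: gene, class ("EE"/"S2"/"S4"), direction
#'   ("A"/"B"/"none"), trigger_group.
#' @export
classify_ase <- function(as_tab, design, s2_band = c(0.31, 0.68),
                         s4_band = c(0.2, 0.8),
                         gm_mode = c("mirrored", "direct")) {
  gm_mode <- match.arg(gm_mode)
  design <- validate_design(design)
  grp <- design_groups(design)[match(as_tab$sample, design$sample_id)]
  if (anyNA(grp))
    stop("samples not in design: ",
         paste(unique(as_tab$sample[is.na(grp)]), collapse = ", "))
  sp <- split(seq_len(nrow(as_tab)), as_tab$gene)
  res <- lapply(names(sp), function(g) {
    i <- sp[[g]]
    cls <- "EE"; dir <- "none"; trig <- NA_character_
    for (k in unique(grp[i])) {
      j <- i[grp[i] == k]
      a <- as_tab$as[j]
      m <- as_tab$masked[j]
      if (any(m)) next                    # masked replicate = unbiased
      if (all(a > 0.5)) {
        side <- "A"; gm_val <- .gm(a)
        hit4 <- gm_val > s4_band[2]
        hit2 <- gm_val > s2_band[2]
      } else if (all(a < 0.5)) {
        side <- "B"
        if (gm_mode == "mirrored") {
          gm_val <- .gm(1 - a)
          hit4 <- gm_val > 1 - s4_band[1]
          hit2 <- gm_val > 1 - s2_band[1]
        } else {
          gm_val <- .gm(a)
          hit4 <- gm_val < s4_band[1]
          hit2 <- gm_val < s2_band[1]
        }
      } else next                          # replicates disagree on side
      if (hit4 && cls != "S4") { cls <- "S4"; dir <- side; trig <- k }
      else if (hit2 && cls == "EE") { cls <- "S2"; dir <- side; trig <- k }
    }
    data.frame(gene = g, class = cls, direction = dir, trigger_group = trig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Chromosome and nuclear read ratios
#'
#' CRR(c) = sum of nucleus-A FPKM over genes of contig c divided by the
#' nucleus-B sum; NRR is the genome-wide ratio.
#'
#' @param fpkm_a,fpkm_b named (gene) numeric vectors on the same genes.
#' @param contigs named character vector, gene -> contig.
#' @return list: `crr` (data.frame contig, crr), `nrr` (scalar; NA when
#'   the denominator is zero).
#' @export
compute_crr_nrr <- function(fpkm_a, fpkm_b, contigs) {
  genes <- names(fpkm_a)
  if (!identical(genes, names(fpkm_b)))
    stop("fpkm_a and fpkm_b must be aligned on the same genes")
  ctg <- contigs[genes]
  sa <- tapply(fpkm_a, ctg, sum)
  sb <- tapply(fpkm_b, ctg, sum)
  crr <- data.frame(contig = names(sa),
                    crr = ifelse(sb > 0, sa / sb, NA_real_),
                    stringsAsFactors = FALSE, row.names = NULL)
  tb <- sum(fpkm_b)
  nrr <- if (tb > 0) sum(fpkm_a) / tb else NA_real_
  list(crr = crr, nrr = nrr)
}
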