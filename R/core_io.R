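## Readers/writers for the tabular formats the pipeline touches, plus the
## run configuration.  All tables are plain TSV; variants additionally
## accept a (subset of) VCF.  Coordinates are 1-based inclusive both on
## disk and in memory, the convention of VCF and of GenomicRanges.

#' Construct and validate a sample design
#'
#' A sample design ties every RNA-seq sample to a developmental stage, an
#' optional tissue type, a replicate number, and a flag marking the
#' vegetative mycelium (VM) baseline.  Samples sharing (stage, tissue)
#' form a replicate group; fold-change and allele-ratio rules all operate
#' on these groups.
#'
#' @param sample_id character vector of unique sample labels.
#' @param stage character vector of stage labels (e.g. VM, P1, P3, YFB, FB).
#' @param tissue optional character vector of tissue labels; `NA` for
#'   unfractionated samples.
#' @param replicate positive integer replicate index within the group.
#' @param is_vm logical; `TRUE` for vegetative-mycelium samples.
#' @return a `data.frame` of class `fs_design`.
#' @export
sample_design <- function(sample_id, stage, tissue = NA_character_,
                          replicate = 1L, is_vm = stage == "VM") {
  d <- data.frame(sample_id = as.character(sample_id),
                  stage = as.character(stage),
                  tissue = as.character(tissue),
                  replicate = as.integer(replicate),
                  is_vm = as.logical(is_vm),
                  stringsAsFactors = FALSE)
  validate_design(d)
}

validate_design <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("sample_id", "stage", "tissue", "replicate", "is_vm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sample design lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (any(d$replicate < 1L) || anyNA(d$replicate))
    stop("replicate must be a positive integer")
  if (all(d$is_vm))
    stop("design needs at least one non-VM sample group")
  class(d) <- c("fs_design", "data.frame")
  d
}

#' Group key (stage, tissue) per design row
#' @param design an `fs_design`.
#' @return character vector of group keys.
#' @export
design_groups <- function(design) {
  tis <- ifelse(is.na(design$tissue) | design$tissue == "", "", design$tissue)
  paste0(design$stage, ifelse(tis == "", "", paste0(".", tis)))
}

#' Construct and validate an expression matrix
#'
#' Ties a nonnegative gene x sample FPKM matrix to its sample design.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).
#' @param design an `fs_design` covering every column.
#' @return object of class `fs_expression` with elements `values`, `design`.
#' @export
expression_matrix <- function(values, design) {
  design <- validate_design(design)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("expression matrix needs unique gene rownames")
  if (is.null(colnames(values)))
    stop("expression matrix needs sample colnames")
  if (any(values < 0, na.rm = TRUE))
    stop("negative expression values are not allowed")
  extra <- setdiff(colnames(values), design$sample_id)
  if (length(extra))
    stop("samples absent from design: ", paste(extra, collapse = ", "))
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  class(design) <- c("fs_design", "data.frame")
  structure(list(values = values, design = design), class = "fs_expression")
}

#' @export
print.fs_expression <- function(x, ...) {
  cat(sprintf("fs_expression: %d genes x %d samples (%d groups, %s VM)\n",
              nrow(x$values), ncol(x$values),
              length(unique(design_groups(x$design))),
              if (any(x$design$is_vm)) "with" else "no"))
  invisible(x)
}

#' Read an expression matrix and its design from TSV
#'
#' The matrix file is tab-separated with gene IDs in the first column and
#' a header of sample IDs; the design file has columns
#' sample_id/stage/tissue/replicate/is_vm.
#'
#' @param path matrix TSV.
#' @param design_path design TSV.
#' @return an `fs_expression`.
#' @export
read_expression <- function(path, design_path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene column plus samples")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  des <- read.delim(design_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  des$is_vm <- as.logical(des$is_vm)
  expression_matrix(m, des)
}

#' Write an expression matrix (and optionally its design) to TSV
#' @param expr an `fs_expression`.
#' @param path matrix TSV destination.
#' @param design_path optional design TSV destination.
#' @export
write_expression <- function(expr, path, design_path = NULL) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    write.table(as.data.frame(expr$design), design_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a variant table
#'
#' Biallelic SNPs distinguishing the two parental genomes: at every site
#' parent A (PC15-like) and parent B (PC9-like) carry different bases.
#'
#' @param contig,position,allele_a,allele_b site coordinates (1-based) and
#'   the two parental bases.
#' @return `data.frame` of class `fs_variants`, sorted by (contig, position).
#' @export
variant_table <- function(contig, position, allele_a, allele_b) {
  v <- data.frame(contig = as.character(contig),
                  position = as.integer(position),
                  allele_a = toupper(as.character(allele_a)),
                  allele_b = toupper(as.character(allele_b)),
                  stringsAsFactors = FALSE)
  bad <- !(v$allele_a %in% c("A", "C", "G", "T")) |
         !(v$allele_b %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("non-ACGT allele at row(s) ", paste(which(bad), collapse = ", "))
  key <- paste(v$contig, v$position)
  if (anyDuplicated(key))
    stop("duplicate variant position: ", key[duplicated(key)][1])
  v <- v[order(v$contig, v$position), , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("fs_variants", "data.frame")
  v
}

#' Read parental SNPs from VCF or 4-column TSV
#'
#' Accepts either a VCF (only CHROM/POS/REF/ALT are consumed; REF is
#' parent A, ALT parent B) or a headered TSV with columns
#' contig/position/allele_a/allele_b.  Indels and multiallelic records are
#' dropped with a message reporting the count.
#'
#' @param path input file.
#' @return an `fs_variants` table.
#' @export
read_variants <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || all(grepl("^\\s*$", lines))) {
    warning("empty variant file: ", path)
    return(variant_table(character(), integer(), character(), character()))
  }
  is_vcf <- grepl("^##", lines[1]) || grepl("^#CHROM", lines[1])
  if (is_vcf) {
    body <- lines[!grepl("^#", lines)]
    if (!length(body))
      return(variant_table(character(), integer(), character(), character()))
    fld <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fld)
    if (any(nf < 5))
      stop("malformed VCF line ", which(grepl("^#", lines) == FALSE)[which(nf < 5)[1]],
           " in ", path)
    chrom <- vapply(fld, `[[`, "", 1L)
    pos <- suppressWarnings(as.integer(vapply(fld, `[[`, "", 2L)))
    ref <- toupper(vapply(fld, `[[`, "", 4L))
    alt <- toupper(vapply(fld, `[[`, "", 5L))
    if (anyNA(pos)) stop("malformed POS in VCF line ", which(is.na(pos))[1])
    snp <- nchar(ref) == 1L & nchar(alt) == 1L &
           ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    if (any(!snp))
      message(sum(!snp), " non-SNP (indel/multiallelic) record(s) dropped")
    variant_table(chrom[snp], pos[snp], ref[snp], alt[snp])
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("contig", "position", "allele_a", "allele_b")
    if (!all(need %in% names(tab)))
      stop("variant TSV needs columns: ", paste(need, collapse = ", "))
    keep <- nchar(tab$allele_a) == 1L & nchar(tab$allele_b) == 1L
    if (any(!keep)) message(sum(!keep), " non-SNP record(s) dropped")
    tab <- tab[keep, , drop = FALSE]
    variant_table(tab$contig, tab$position, tab$allele_a, tab$allele_b)
  }
}

#' Write a variant table as 4-column TSV
#' @param variants an `fs_variants`.
#' @param path destination.
#' @export
write_variants <- function(variants, path) {
  write.table(as.data.frame(variants), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an all-vs-all protein hit table
#'
#' Tabular alignment format (BLAST outfmt-6 like) extended with
#' nident/qlen/slen; coverage fractions are derived if absent.
#'
#' @param path TSV with a header row.
#' @return validated `data.frame` of class `fs_hits`.
#' @export
read_hits <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  hit_table(tab)
}

#' Validate a hit table
#' @param tab data.frame with columns query, target, bitscore, evalue,
#'   nident, alnlen, qlen, slen (qcov/scov derived if missing).
#' @return `fs_hits` data.frame.
#' @export
hit_table <- function(tab) {
  need <- c("query", "target", "bitscore", "evalue", "nident", "alnlen",
            "qlen", "slen")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  if (any(tab$qlen <= 0 | tab$slen <= 0)) stop("zero-length protein in hit table")
  if (any(tab$nident > tab$alnlen)) stop("nident exceeds alnlen")
  if (any(tab$evalue < 0)) stop("negative e-value")
  if (is.null(tab$qcov)) tab$qcov <- pmin(1, tab$alnlen / tab$qlen)
  if (is.null(tab$scov)) tab$scov <- pmin(1, tab$alnlen / tab$slen)
  class(tab) <- c("fs_hits", "data.frame")
  tab
}

#' Default pipeline configuration
#'
#' Every numeric threshold of every stage, with defaults equal to the
#' published values so that a default run reproduces the published rules:
#' FPKM fold-change thresholds 2/4 with FPKM > 4 and VM exclusion; Phred
#' floor 30; Hamming-distance indecisiveness rules (>1 both, >15 any,
#' tie); AS masking (FPKM < 2, decisive < 16, indecisive > 80%); S2/S4
#' bands 0.31/0.68 and 0.2/0.8 on replicate geometric means; RBH e-value
#' 1e-5 with the bitscore/3 + hit-overlap spurious filter; asymmetric
#' coverage 0.2/0.8; MCL inflation 2.0; conserved orthogroups in >= 4
#' species at proportion >= 0.5.  Editing-candidate thresholds
#' (min_vrs/min_rs/min_rvf) are artifact defaults, not published values.
#'
#' @param ... name = value overrides of any default.
#' @return named list of class `fs_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # devexpr
    fc_threshold = 4, min_fpkm = 4, fc_floor = 0.1,
    # variant partition
    min_phred = 30L,
    min_vrs = 3L, min_rs = 10L, min_rvf = 0.1,
    # read assignment
    max_hd_decisive = 1L, max_hd_divergent = 15L,
    divergent_rule = c("any", "closer")[1],
    # AS ratio masking
    as_min_fpkm = 2, as_min_decisive = 16L, as_max_indecisive_frac = 0.8,
    # ASE classification
    s2_lo = 0.31, s2_hi = 0.68, s4_lo = 0.2, s4_hi = 0.8,
    gm_mode = c("mirrored", "direct")[1],
    # TAI
    tai_log_mode = c("log2p1", "log2_drop")[1],
    age_scale = c("raw", "normalized")[1],
    # orthology
    evalue_cutoff = 1e-5, long_cov = 0.2, short_cov = 0.8,
    mcl_inflation = 2.0, mcl_tol = 1e-6, mcl_max_iter = 100L,
    spurious_bitscore_factor = 3, spurious_overlap = 0.5,
    min_dev_species = 4L, min_dev_prop = 0.5,
    prop_denominator = c("present", "all")[1],
    # simulation
    sim_n_genes = 2000L, sim_frac_dev = 0.2,
    sim_fc_min = 4, sim_fc_max = 16, sim_noise_sd = 0.25,
    sim_frac_vm_max = 0.05, sim_depth_mean = 200,
    sim_indecisive_frac = 0.2,
    io = list())
  over <- list(...)
  unknown <- setdiff(names(over), c(names(cfg), "io"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_phred >= 0, cfg$max_hd_decisive >= 0,
            cfg$max_hd_divergent >= cfg$max_hd_decisive,
            cfg$s2_lo < 0.5, cfg$s2_hi > 0.5, cfg$s4_lo <= cfg$s2_lo,
            cfg$s4_hi >= cfg$s2_hi, cfg$as_max_indecisive_frac >= 0,
            cfg$as_max_indecisive_frac <= 1, cfg$mcl_inflation > 1,
            cfg$long_cov >= 0, cfg$long_cov <= 1, cfg$short_cov >= 0,
            cfg$short_cov <= 1, cfg$min_dev_prop >= 0, cfg$min_dev_prop <= 1,
            cfg$fc_threshold >= 1, cfg$min_rvf >= 0, cfg$min_rvf <= 1)
  class(cfg) <- "fs_config"
  cfg
}

#' Read / write a pipeline configuration (JSON)
#' @param path JSON file.
#' @return an `fs_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, cfg[setdiff(names(cfg), "io")]) -> out
  out$io <- as.list(cfg$io)
  out
}

#' @rdname read_config
#' @param cfg an `fs_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
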