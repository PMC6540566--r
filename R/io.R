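# Readers and writers for phenotype, covariate, genotype (TSV / PLINK BED /
# VCF dosage) and gene-set inputs.  All readers reject malformed records
# with the offending line number rather than coercing silently; sample
# joining downstream is always by id, never positional.

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a phenotype table
#'
#' Delimited file with header columns `sample_id`, `interval`, `event`.
#' Malformed records (non-integer interval, event outside \{0, 1\},
#' duplicate ids) raise an error citing the file line number (header =
#' line 1).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `sample_id` (character), `interval`
#'   (integer) and `event` (integer).
#' @export
read_phenotype <- function(path) {
  tb <- read_tsv_quiet(path)
  need <- c("sample_id", "interval", "event")
  if (!all(need %in% names(tb))) {
    stop(path, ": expected header columns ", paste(need, collapse = ", "))
  }
  line <- seq_len(nrow(tb)) + 1L
  bad <- which(!is.numeric(tb$interval) | is.na(tb$interval) |
                 tb$interval != round(tb$interval) | tb$interval < 1)
  if (length(bad)) {
    stop(path, ": non-integer interval on line ",
         paste(line[bad], collapse = ", "))
  }
  bad <- which(!tb$event %in% c(0, 1))
  if (length(bad)) {
    stop(path, ": event not in {0,1} on line ", paste(line[bad], collapse = ", "))
  }
  dup <- which(duplicated(tb$sample_id))
  if (length(dup)) {
    stop(path, ": duplicate sample_id on line ", paste(line[dup], collapse = ", "))
  }
  tibble::tibble(sample_id = as.character(tb$sample_id),
                 interval = as.integer(tb$interval),
                 event = as.integer(tb$event))
}

#' Write a phenotype table
#' @param pheno Tibble with `sample_id`, `interval`, `event`.
#' @param path Output path (tab-separated, header included).
#' @export
write_phenotype <- function(pheno, path) {
  readr::write_tsv(pheno[c("sample_id", "interval", "event")], path)
  invisible(path)
}

#' Read a covariate table
#'
#' `sample_id` column plus numeric covariate columns.
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  tb <- read_tsv_quiet(path)
  if (!"sample_id" %in% names(tb)) stop(path, ": no sample_id column")
  vals <- tb[setdiff(names(tb), "sample_id")]
  bad <- names(vals)[!vapply(vals, is.numeric, TRUE)]
  if (length(bad)) {
    stop(path, ": non-numeric covariate column(s): ", paste(bad, collapse = ", "))
  }
  tb$sample_id <- as.character(tb$sample_id)
  tb
}

#' Read a genotype/dosage matrix
#'
#' Three on-disk formats are supported:
#' * `tsv` — header `sample_id` then one column per variant; `NA` or empty
#'   cells mark missing dosages.
#' * `vcf` — dosages from the per-genotype `DS` field when present,
#'   otherwise additive coding of `GT` (`./.` missing). Multi-allelic
#'   records are skipped with a warning.
#' * `bed` — binary PLINK bed/bim/fam trio (`path` names the `.bed`;
#'   companions are found by extension). Dosage counts the A1 allele;
#'   the PLINK missing code becomes `NA`.
#'
#' @param path Input path.
#' @param format One of `"tsv"`, `"vcf"`, `"bed"`.
#' @return Numeric matrix (samples x variants) with sample ids as
#'   rownames and variant ids as colnames.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "bed")) {
  format <- match.arg(format)
  switch(format,
         tsv = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path),
         bed = read_genotypes_bed(path))
}

read_genotypes_tsv <- function(path) {
  tb <- read_tsv_quiet(path)
  if (!"sample_id" %in% names(tb)) stop(path, ": no sample_id column")
  ids <- as.character(tb$sample_id)
  G <- as.matrix(tb[setdiff(names(tb), "sample_id")])
  if (!is.numeric(G)) stop(path, ": non-numeric dosage values")
  rownames(G) <- ids
  G
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sum(!bi), " multi-allelic record(s) skipped")
    v <- v[bi, ]
  }
  ids <- vcfR::getID(v)
  ids[is.na(ids) | ids == "."] <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))[is.na(ids) | ids == "."]
  has_ds <- any(grepl("(^|:)DS(:|$)", v@gt[, 1]))
  if (has_ds) {
    M <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    M <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  G <- t(M)
  colnames(G) <- ids
  G
}

# 2-bit PLINK codes per byte, low bits first: 0 -> 2 copies of A1,
# 1 -> missing, 2 -> het, 3 -> 0 copies
plink_lut <- function() {
  codes <- c(2, NA, 1, 0)
  t(vapply(0:255, function(b) {
    codes[1 + c(bitwAnd(b, 3L),
                bitwAnd(bitwShiftR(b, 2L), 3L),
                bitwAnd(bitwShiftR(b, 4L), 3L),
                bitwAnd(bitwShiftR(b, 6L), 3L))]
  }, numeric(4)))
}

read_genotypes_bed <- function(path) {
  stem <- sub("\\.bed$", "", path)
  bed <- paste0(stem, ".bed"); bim <- paste0(stem, ".bim"); fam <- paste0(stem, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  fam_tb <- utils::read.table(fam, header = FALSE, colClasses = "character")
  ids <- fam_tb[[2]]
  bim_tb <- utils::read.table(bim, header = FALSE, colClasses = "character")
  vids <- bim_tb[[2]]
  n <- length(ids); m <- length(vids)
  bpv <- ceiling(n / 4)
  raw <- readBin(bed, what = "raw", n = 3 + m * bpv)
  if (length(raw) < 3 + m * bpv) stop(bed, ": truncated file")
  if (!identical(as.integer(raw[1:2]), c(0x6cL, 0x1bL))) {
    stop(bed, ": not a PLINK bed file (bad magic)")
  }
  if (as.integer(raw[3]) != 1L) stop(bed, ": only SNP-major bed files supported")
  lut <- plink_lut()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  G <- matrix(NA_real_, n, m, dimnames = list(ids, vids))
  for (j in seq_len(m)) {
    vals <- as.vector(t(lut[body[, j] + 1L, , drop = FALSE]))
    G[, j] <- vals[seq_len(n)]
  }
  G
}

#' Read gene-set definitions
#'
#' Two-column delimited file `set_id`, `variant_id`.
#' @param path Input path.
#' @return A tibble with those two columns.
#' @export
read_gene_sets <- function(path) {
  tb <- read_tsv_quiet(path)
  if (!all(c("set_id", "variant_id") %in% names(tb))) {
    stop(path, ": expected columns set_id, variant_id")
  }
  tibble::tibble(set_id = as.character(tb$set_id),
                 variant_id = as.character(tb$variant_id))
}

#' Write a variant scan result table
#'
#' Tab-separated, columns exactly `variant_id, n, maf, stat, pvalue,
#' fwer_p, qvalue, beta_hat, status`; missing numerics are written `NA`.
#'
#' @param scan A [scan_variants()] tibble.
#' @param path Output path.
#' @export
write_results <- function(scan, path) {
  cols <- c("variant_id", "n", "maf", "stat", "pvalue", "fwer_p",
            "qvalue", "beta_hat", "status")
  miss <- setdiff(cols, names(scan))
  if (length(miss)) stop("scan table lacks column(s): ", paste(miss, collapse = ", "))
  readr::write_tsv(as.data.frame(scan)[cols], path, na = "NA")
  invisible(path)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact p-value for a biallelic genotype count triple,
#' summing the probabilities of all heterozygote counts (given the allele
#' counts) whose conditional probability does not exceed that of the
#' observed configuration.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major hom, het, minor hom).
#' @return The exact p-value.
#' @export
hwe_exact_pvalue <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_minor <- 2 * n_bb + n_ab
  n_major <- 2 * n_aa + n_ab
  if (n_minor > n_major) { tmp <- n_minor; n_minor <- n_major; n_major <- tmp }
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(n_ab = h | allele counts) up to a constant
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- (n_major - h) / 2
    h * log(2) - lfactorial(h) - lfactorial(hom_min) - lfactorial(hom_maj)
  }, 1.0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality-control filter
#'
#' Optional pre-scan filters on call rate, Hardy-Weinberg exact-test
#' p-value and minor allele frequency. All thresholds default to "off"
#' (keep everything).
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param maf_min Minimum MAF (variants strictly below are dropped).
#' @param callrate_min Minimum fraction of non-missing calls.
#' @param hwe_min Minimum HWE exact p-value (hard-called dosages only;
#'   dosages are rounded for the genotype counts).
#' @return A tibble per variant: `variant_id`, `callrate`, `maf`,
#'   `hwe_p`, `keep`.
#' @export
qc_filter <- function(genotypes, maf_min = 0, callrate_min = 0, hwe_min = 0) {
  G <- as.matrix(genotypes)
  vid <- colnames(G)
  if (is.null(vid)) vid <- paste0("v", seq_len(ncol(G)))
  stats_tb <- purrr::map_dfr(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    cr <- mean(!is.na(g))
    f <- if (any(!is.na(g))) mean(g, na.rm = TRUE) / 2 else NA_real_
    maf <- if (is.na(f)) NA_real_ else min(f, 1 - f)
    hw <- NA_real_
    if (hwe_min > 0 && cr > 0) {
      gr <- round(g[!is.na(g)])
      hw <- hwe_exact_pvalue(sum(gr == 0), sum(gr == 1), sum(gr == 2))
    }
    tibble::tibble(variant_id = vid[j], callrate = cr, maf = maf, hwe_p = hw)
  })
  stats_tb$keep <- (stats_tb$callrate >= callrate_min) &
    (is.na(stats_tb$maf) | stats_tb$maf >= maf_min) &
    (hwe_min <= 0 | (!is.na(stats_tb$hwe_p) & stats_tb$hwe_p >= hwe_min))
  stats_tb
}
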