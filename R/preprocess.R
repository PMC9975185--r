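# Reading, harmonizing, QC-filtering and joining GWAS summary statistics
# with LD reference information.

.GWAS_COLS <- c(snp_id = "SNP", effect_allele = "A1", other_allele = "A2",
                effect = "BETA", se = "SE", z = "Z", n = "N", maf = "MAF",
                info = "INFO", chrom = "CHR", pos = "BP")

#' Read a GWAS summary-statistics table
#'
#' Headered whitespace- or tab-delimited text (gzip-transparent). Column
#' names are mapped through `cols`; only columns present in the file are
#' kept. Either a signed effect with its standard error or a z-score must be
#' present, along with the per-SNP sample size.
#'
#' @param path file path.
#' @param cols named character vector mapping internal names (`snp_id`,
#'   `effect_allele`, `other_allele`, `effect`, `se`, `z`, `n`, `maf`,
#'   `info`, `chrom`, `pos`) to the column names used in the file.
#' @return tibble with the internal column names.
#' @export
read_gwas <- function(path, cols = .GWAS_COLS) {
  raw <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  found <- cols[cols %in% names(raw)]
  if (!"snp_id" %in% names(found)) abort("no SNP id column found")
  out <- raw[, unname(found)]
  names(out) <- names(found)
  out$snp_id <- as.character(out$snp_id)
  if (anyDuplicated(out$snp_id)) {
    warn("duplicated SNP ids; keeping first occurrence")
    out <- out[!duplicated(out$snp_id), ]
  }
  as_tibble(out)
}

#' Standardize marginal effects
#'
#' Converts effects to the standardized per-SD scale used by the model:
#' `tau_hat = z / sqrt(n)` with `z = effect / se` when no z-score column is
#' present; the standard error becomes `1 / sqrt(n)`. Rows without a sample
#' size, or with `se <= 0`, are rejected (reasons in attribute `rejected`).
#'
#' @param table a tibble from [read_gwas()].
#' @return the table with columns `tau` and `se` replaced, and a `rejected`
#'   attribute listing removed rows and reason codes.
#' @export
standardize_effects <- function(table) {
  t <- as_tibble(table)
  has_z <- "z" %in% names(t) && !all(is.na(t$z))
  rej <- tibble(snp_id = character(0), reason = character(0))
  if (!"n" %in% names(t)) abort("sample size column 'n' is required")
  bad_n <- is.na(t$n) | t$n <= 0
  if (!has_z) {
    if (!all(c("effect", "se") %in% names(t)))
      abort("need either a z column or effect + se columns")
    bad_se <- is.na(t$se) | t$se <= 0
    z <- ifelse(bad_se, NA_real_, t$effect / t$se)
    rej <- bind_rows(rej,
                     tibble(snp_id = t$snp_id[bad_se & !bad_n], reason = "SE"))
  } else {
    z <- t$z
    bad_se <- is.na(z)
    rej <- bind_rows(rej,
                     tibble(snp_id = t$snp_id[bad_se & !bad_n], reason = "Z"))
  }
  rej <- bind_rows(tibble(snp_id = t$snp_id[bad_n], reason = "N"), rej)
  keep <- !bad_n & !bad_se
  out <- t[keep, ]
  out$tau <- z[keep] / sqrt(out$n)
  out$se <- 1 / sqrt(out$n)
  out$z <- z[keep]
  attr(out, "rejected") <- rej
  out
}

.AMBIGUOUS <- c("AT", "TA", "CG", "GC")

#' Harmonize alleles across the two GWAS and the LD reference
#'
#' Restricts to the SNPs common to both tables and the reference, removes
#' strand-ambiguous (A/T, C/G) SNPs, flips the sign of the second table's
#' effects where its effect/other alleles are swapped relative to the first,
#' drops SNPs whose allele pairs cannot be reconciled, and orders the output
#' to match the reference.
#'
#' @param t1,t2 standardized tables (see [standardize_effects()]).
#' @param ref an LD reference from [read_ld_reference()].
#' @return list with aligned `t1` and `t2`; attribute `dropped` records
#'   removed SNPs and reasons.
#' @export
harmonize_alleles <- function(t1, t2, ref) {
  ids <- intersect(intersect(t1$snp_id, t2$snp_id), ref$ld$snp_id)
  if (!length(ids)) abort("no common SNPs between the two GWAS and the LD reference")
  ord <- ref$ld$snp_id[ref$ld$snp_id %in% ids]
  a1 <- t1[match(ord, t1$snp_id), ]
  a2 <- t2[match(ord, t2$snp_id), ]
  up <- function(x) toupper(as.character(x))
  pair1 <- paste0(up(a1$effect_allele), up(a1$other_allele))
  ambiguous <- pair1 %in% .AMBIGUOUS
  same <- up(a2$effect_allele) == up(a1$effect_allele) &
    up(a2$other_allele) == up(a1$other_allele)
  swapped <- up(a2$effect_allele) == up(a1$other_allele) &
    up(a2$other_allele) == up(a1$effect_allele)
  mismatch <- !same & !swapped
  dropped <- tibble(snp_id = ord[ambiguous | mismatch],
                    reason = ifelse(ambiguous[ambiguous | mismatch],
                                    "ambiguous", "allele mismatch"))
  keep <- !ambiguous & !mismatch
  a1 <- a1[keep, ]
  a2 <- a2[keep, ]
  flip <- swapped[keep]
  for (col in intersect(c("tau", "effect", "z"), names(a2)))
    a2[[col]][flip] <- -a2[[col]][flip]
  a2$effect_allele[flip] <- a1$effect_allele[flip]
  a2$other_allele[flip] <- a1$other_allele[flip]
  out <- list(t1 = a1, t2 = a2)
  attr(out, "dropped") <- dropped
  out
}

#' Quality-control filter
#'
#' Removes SNPs with low minor-allele frequency, low imputation quality,
#' atypically small per-SNP sample size (below `n_frac` of the 90th
#' percentile over all SNPs), position inside the MHC region, or an
#' implausibly large standardized effect.
#'
#' @param t a standardized table.
#' @param maf_min minimum minor-allele frequency (rows lacking `maf` are
#'   kept).
#' @param info_min minimum imputation INFO score (rows lacking `info` are
#'   kept).
#' @param n_frac multiplier of the 90th percentile of `n` below which SNPs
#'   are dropped.
#' @param mhc `c(chrom, start, end)` of the major histocompatibility complex
#'   (GRCh37 by default); applied when `chrom`/`pos` are present.
#' @param tau_max maximum absolute standardized effect.
#' @return the filtered table; attribute `report` tabulates removals per
#'   rule, attribute `reasons` gives per-SNP reasons.
#' @export
qc_filter <- function(t, maf_min = 0.05, info_min = 0.9, n_frac = 0.67,
                      mhc = c(6, 25e6, 34e6), tau_max = 0.1) {
  t <- as_tibble(t)
  rules <- list()
  if (nrow(t)) {
    rules$MAF <- if ("maf" %in% names(t))
      !is.na(t$maf) & pmin(t$maf, 1 - t$maf) < maf_min else rep(FALSE, nrow(t))
    rules$INFO <- if ("info" %in% names(t))
      !is.na(t$info) & t$info < info_min else rep(FALSE, nrow(t))
    rules$N <- if ("n" %in% names(t))
      t$n < n_frac * quantile(t$n, 0.9, names = FALSE) else rep(FALSE, nrow(t))
    rules$MHC <- if (all(c("chrom", "pos") %in% names(t)))
      !is.na(t$chrom) & t$chrom == mhc[1] & t$pos >= mhc[2] & t$pos <= mhc[3]
      else rep(FALSE, nrow(t))
    rules$EFFECT <- if ("tau" %in% names(t))
      abs(t$tau) > tau_max else rep(FALSE, nrow(t))
  } else {
    rules <- list(MAF = logical(0), INFO = logical(0), N = logical(0),
                  MHC = logical(0), EFFECT = logical(0))
  }
  drop <- Reduce(`|`, rules)
  reason <- vapply(seq_len(nrow(t)), function(i) {
    hit <- names(rules)[vapply(rules, `[`, logical(1), i)]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  out <- t[!drop, ]
  attr(out, "report") <- tibble(rule = names(rules),
                                count = vapply(rules, sum, numeric(1)))
  attr(out, "reasons") <- tibble(snp_id = t$snp_id[drop],
                                 reason = reason[drop])
  out
}

#' Read an LD reference
#'
#' Accepts either a tab-delimited `{SNP, L2, NTAG}` table or an LDSC-style
#' `.l2.ldscore` file (columns `CHR, SNP, BP, L2`) with tag counts supplied
#' separately. The tagging sets come from a sparse pair file with two
#' columns of SNP ids (self-pairs implied; symmetric closure applied). With
#' no pair file the reference is self-tagging only (`n_tagged` forced
#' consistent).
#'
#' @param path path to the LD-score table.
#' @param pairs_path optional path to the tag-pair file.
#' @param ntag optional vector of tag counts (when `path` is an `.l2.ldscore`
#'   dialect without an `NTAG` column), aligned to the rows of `path`.
#' @return list of class `mrci_ld_reference`: `ld` (tibble `snp_id`,
#'   `ld_score`, `n_tagged`) and `tags` (named list of tagged snp ids,
#'   self-inclusive).
#' @export
read_ld_reference <- function(path, pairs_path = NULL, ntag = NULL) {
  raw <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  snp_col <- intersect(c("SNP", "snp_id"), names(raw))[1]
  l2_col <- intersect(c("L2", "ld_score"), names(raw))[1]
  if (is.na(snp_col) || is.na(l2_col)) abort("LD reference needs SNP and L2 columns")
  ld <- tibble(snp_id = as.character(raw[[snp_col]]),
               ld_score = as.numeric(raw[[l2_col]]))
  ntag_col <- intersect(c("NTAG", "n_tagged"), names(raw))[1]
  if (!is.na(ntag_col)) ld$n_tagged <- as.integer(raw[[ntag_col]])
  else if (!is.null(ntag)) ld$n_tagged <- as.integer(ntag)
  else ld$n_tagged <- NA_integer_

  tags <- setNames(as.list(ld$snp_id), ld$snp_id)  # self-tagging
  if (!is.null(pairs_path)) {
    pr <- readr::read_table(pairs_path, col_names = c("i", "j"),
                            col_types = "cc", skip = ld_pairs_skip(pairs_path),
                            progress = FALSE)
    pr <- pr[pr$i %in% ld$snp_id & pr$j %in% ld$snp_id, ]
    both <- tibble(a = c(pr$i, pr$j, ld$snp_id), b = c(pr$j, pr$i, ld$snp_id))
    tags <- split(both$b, factor(both$a, levels = ld$snp_id))
    tags <- lapply(tags, unique)
  }
  counted <- lengths(tags)[ld$snp_id]
  if (all(is.na(ld$n_tagged))) ld$n_tagged <- as.integer(counted)
  else if (any(ld$n_tagged != counted, na.rm = TRUE))
    warn("NTAG disagrees with the tag-pair file; keeping NTAG for the model, pairs for score sums")
  ld$ld_score <- pmax(ld$ld_score, 1)
  ld$n_tagged <- pmax(ld$n_tagged, 1L)
  structure(list(ld = ld, tags = tags), class = "mrci_ld_reference")
}

ld_pairs_skip <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("SNP", first, ignore.case = TRUE)) 1L else 0L
}

#' Assemble the analysis dataset
#'
#' Joins two harmonized, standardized, QC-filtered tables with the LD
#' reference into an [mrci_data()] dataset: one record per retained SNP in
#' reference order, tagging sets restricted to retained SNPs (LD score and
#' tag count kept at their reference values), and scalar sample sizes taken
#' as the median per-SNP `n` of each GWAS.
#'
#' @param t1,t2 aligned tables (see [harmonize_alleles()]).
#' @param ref an `mrci_ld_reference`.
#' @return an [mrci_data()] dataset.
#' @export
build_dataset <- function(t1, t2, ref) {
  stopifnot(identical(t1$snp_id, t2$snp_id))
  ids <- t1$snp_id
  hit <- ids %in% ref$ld$snp_id
  if (any(!hit)) {
    warn(paste0(sum(!hit), " SNP(s) missing from the LD reference; dropped"))
    ids <- ids[hit]
  }
  ord <- ref$ld$snp_id[ref$ld$snp_id %in% ids]
  i1 <- match(ord, t1$snp_id)
  ldr <- ref$ld[match(ord, ref$ld$snp_id), ]
  pos <- setNames(seq_along(ord), ord)
  tag_idx <- unname(lapply(ref$tags[ord], function(tt) {
    v <- unname(pos[tt[tt %in% ord]])
    sort(v)
  }))
  mrci_data(snp_id = ord,
            tau1 = t1$tau[i1], tau2 = t2$tau[match(ord, t2$snp_id)],
            ld_score = ldr$ld_score, n_tagged = ldr$n_tagged,
            tag_idx = tag_idx,
            n1 = median(t1$n, na.rm = TRUE), n2 = median(t2$n, na.rm = TRUE))
}

#' Write / read a dataset in the exchange formats
#'
#' Writes the two GWAS summary tables (`<prefix>_gwas1.tsv`,
#' `<prefix>_gwas2.tsv` with columns SNP, A1, A2, Z, N), the LD reference
#' (`<prefix>_ld.tsv` with SNP, L2, NTAG and `<prefix>_tags.tsv` with the
#' off-diagonal tag pairs), and, when ground truth is attached, the true
#' parameters (`<prefix>_truth.json`). `read_dataset()` reverses the round
#' trip through [read_gwas()], [standardize_effects()],
#' [harmonize_alleles()], [read_ld_reference()] and [build_dataset()].
#'
#' @param data an [mrci_data()] dataset.
#' @param prefix output path prefix.
#' @return `write_dataset()` the prefix, invisibly; `read_dataset()` an
#'   [mrci_data()] dataset.
#' @export
write_dataset <- function(data, prefix) {
  ns <- sample_sizes(data)
  g <- function(tau, n) tibble(SNP = data$snp_id, A1 = "A", A2 = "G",
                               Z = tau * sqrt(n), N = n)
  readr::write_tsv(g(data$tau1, ns[1]), paste0(prefix, "_gwas1.tsv"))
  readr::write_tsv(g(data$tau2, ns[2]), paste0(prefix, "_gwas2.tsv"))
  readr::write_tsv(tibble(SNP = data$snp_id, L2 = data$ld_score,
                          NTAG = data$n_tagged),
                   paste0(prefix, "_ld.tsv"))
  k <- rep.int(seq_len(nrow(data)), lengths(data$tag_idx))
  j <- unlist(data$tag_idx, use.names = FALSE)
  off <- k < j
  readr::write_tsv(tibble(SNP_i = data$snp_id[k[off]],
                          SNP_j = data$snp_id[j[off]]),
                   paste0(prefix, "_tags.tsv"))
  if (!is.null(attr(data, "truth")))
    write_params(attr(data, "truth"), path = paste0(prefix, "_truth.json"))
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  t1 <- standardize_effects(read_gwas(paste0(prefix, "_gwas1.tsv")))
  t2 <- standardize_effects(read_gwas(paste0(prefix, "_gwas2.tsv")))
  ref <- read_ld_reference(paste0(prefix, "_ld.tsv"),
                           pairs_path = paste0(prefix, "_tags.tsv"))
  h <- harmonize_alleles(t1, t2, ref)
  build_dataset(h$t1, h$t2, ref)
}
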