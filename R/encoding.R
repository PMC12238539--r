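#' Collapse a tetraploid or octoploid call to a pseudo-diploid pair
#'
#' Octoploid individuals are genotyped with four allele copies per locus;
#' before model building every call is reduced to a diploid pair so that
#' tetraploids and octoploids share one encoding. A homozygous 4-allele call
#' (e.g. `A,A,A,A`) collapses to the homozygous pair (`A,A`); every mixed
#' composition (`A,T,T,T`, `A,A,T,T`, `A,A,A,T`) collapses to the same
#' heterozygous pair (`A,T`). Calls that are already diploid pass through
#' unchanged.
#'
#' If a 4-allele call carries more than two distinct alleles, the two most
#' frequent alleles are kept; frequency ties are broken by `allele_order`
#' (reference first, then alternative alleles in their declared order).
#'
#' @param call Vector of 2 or 4 allele identifiers (allele strings or 0-based
#'   allele indices), or `NA` for a missing call. Any `NA` component marks the
#'   whole call missing.
#' @param allele_order Optional vector giving the canonical allele order used
#'   to break frequency ties (typically `c(ref, alts)`). When `NULL`, numeric
#'   calls use numeric order and character calls use order of first appearance.
#' @return A length-2 vector (the pseudo-diploid pair), or `NA` if the call is
#'   missing.
#' @examples
#' collapse_to_pseudodiploid(c("A", "A", "T", "T"))  # -> c("A", "T")
#' collapse_to_pseudodiploid(c("A", "A", "A", "A"))  # -> c("A", "A")
#' @export
collapse_to_pseudodiploid <- function(call, allele_order = NULL) {
  if (length(call) == 1 && is.na(call)) return(NA)
  if (!length(call) %in% c(2L, 4L)) {
    abort(sprintf("ploidy %d not supported: calls must have 2 or 4 alleles",
                  length(call)),
          class = "polygp_ploidy_error")
  }
  if (anyNA(call)) return(NA)
  if (length(call) == 2L) return(call)

  cnt <- table(factor(call, levels = unique(call)))
  if (length(cnt) == 1L) return(rep(call[1], 2L))

  alleles <- names(cnt)
  ord <- if (!is.null(allele_order)) {
    match(alleles, as.character(allele_order))
  } else if (is.numeric(call)) {
    as.numeric(alleles)
  } else {
    seq_along(alleles) # first appearance in the call
  }
  keep <- alleles[order(-as.integer(cnt), ord)][1:2]
  keep <- keep[order(ord[match(keep, alleles)])]
  if (is.numeric(call)) keep <- as.numeric(keep)
  keep
}

is_indel_allele <- function(ref, alt) {
  alt == "*" | nchar(alt) != nchar(ref)
}

#' Classify a variant and its encoded columns
#'
#' A variant with one alternative allele is a bi-allelic SNP or indel; a
#' variant with m > 1 alternative alleles is multi-allelic, and each of its m
#' indicator columns is classified separately: substitution alternatives give
#' multi-allelic SNP columns, length-changing alternatives (including the
#' spanning-deletion allele `*`) give multi-allelic indel columns.
#'
#' @param ref Reference allele string.
#' @param alts Character vector of alternative allele strings (length m >= 1).
#' @return A list with `var_class` (one of `biallelic_snp`, `biallelic_indel`,
#'   `multiallelic_snp`, `multiallelic_indel`, `multiallelic_mixed`) and
#'   `column_class`, a length-m character vector.
#' @examples
#' classify_variant("A", c("T", "G", "AT"))
#' @export
classify_variant <- function(ref, alts) {
  if (!nzchar(ref) || any(!nzchar(alts)) || length(alts) < 1) {
    abort("empty allele string in variant record",
          class = "polygp_format_error")
  }
  if (anyDuplicated(c(ref, alts))) {
    abort("alleles must be distinct from the reference and each other",
          class = "polygp_format_error")
  }
  indel <- is_indel_allele(ref, alts)
  if (length(alts) == 1L) {
    cls <- if (indel) "biallelic_indel" else "biallelic_snp"
    return(list(var_class = cls, column_class = cls))
  }
  col_cls <- ifelse(indel, "multiallelic_indel", "multiallelic_snp")
  var_cls <- if (all(indel)) "multiallelic_indel"
             else if (!any(indel)) "multiallelic_snp"
             else "multiallelic_mixed"
  list(var_class = var_cls, column_class = col_cls)
}

#' Encode collapsed diploid calls at one variant into indicator columns
#'
#' A variant with m alternative alleles yields m columns, one per alternative.
#' Within a column only copies of that column's alternative are counted: 0
#' copies in the pseudo-diploid pair is coded 1 (homozygous "reference" with
#' respect to this alternative), 1 copy is coded 0 (heterozygous), 2 copies is
#' coded -1 (homozygous alternative). All other alleles - the reference and
#' every other alternative - count as reference, so e.g. the pair (G, AT) at a
#' locus with alternatives (T, G, AT) codes 1 in the T column and 0 in both
#' the G and AT columns. With m = 1 this reduces to the usual bi-allelic
#' {1, 0, -1} coding.
#'
#' @param ref Reference allele string.
#' @param alts Character vector of m alternative alleles (order fixes column
#'   order).
#' @param calls List of collapsed diploid pairs (length-2 character vectors),
#'   with `NA` entries for missing calls.
#' @return A numeric matrix with `length(calls)` rows and m columns named by
#'   alternative allele; missing calls are `NA` across the row.
#' @examples
#' encode_variant("A", c("T", "G", "AT"),
#'                list(c("T", "G"), c("AT", "AT"), c("A", "A")))
#' @export
encode_variant <- function(ref, alts, calls) {
  stopifnot(is.list(calls))
  alleles <- c(ref, alts)
  m <- length(alts)
  out <- matrix(NA_real_, nrow = length(calls), ncol = m,
                dimnames = list(NULL, alts))
  for (i in seq_along(calls)) {
    pair <- calls[[i]]
    if (length(pair) == 1 && is.na(pair)) next
    if (anyNA(pair)) next
    if (!all(pair %in% alleles)) {
      abort(sprintf("call (%s) contains alleles outside {ref, alts}",
                    paste(pair, collapse = ",")),
            class = "polygp_consistency_error")
    }
    for (t in seq_len(m)) {
      out[i, t] <- 1 - sum(pair == alts[t])
    }
  }
  out
}

#' Encode a panel of raw calls into a genotype matrix
#'
#' Applies pseudo-diploid collapsing and the per-alternative-allele indicator
#' expansion to every locus, producing an individuals x columns matrix of
#' codes in {1, 0, -1} with `NA` marking missing calls. A locus with m
#' alternative alleles contributes m columns, so the encoded matrix has
#' sum(m_i) columns in total.
#'
#' @param calls Character matrix of GT index strings (rows = individuals,
#'   columns = loci, e.g. `"0/1"` or `"0/0/1/2"`; `NA` or any `.` component =
#'   missing), as returned by [read_genotypes()] or [simulate_panel()].
#' @param variant_table Tibble with one row per locus: `variant_id`, `chrom`,
#'   `pos`, `ref` and list-column `alts` (see [read_genotypes()]).
#' @return A `geno_matrix` object: list with `data` (numeric matrix), `columns`
#'   (tibble of per-column metadata incl. `column_class`, `maf`,
#'   `missing_frac`) and `individuals`.
#' @export
encode_genotypes <- function(calls, variant_table) {
  stopifnot(is.matrix(calls), nrow(variant_table) == ncol(calls))
  n <- nrow(calls)
  individuals <- rownames(calls) %||% sprintf("ind_%03d", seq_len(n))

  # GT patterns repeat heavily across loci; collapse each distinct pattern
  # once and index into the result
  ug <- unique(as.vector(calls))
  upairs <- vapply(ug, function(g) {
    if (is.na(g)) return(c(NA_integer_, NA_integer_))
    idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    if (anyNA(idx)) return(c(NA_integer_, NA_integer_))
    as.integer(collapse_to_pseudodiploid(idx))
  }, integer(2))
  idx_mat <- matrix(match(calls, ug), nrow = n)

  blocks <- vector("list", nrow(variant_table))
  metas <- vector("list", nrow(variant_table))
  for (j in seq_len(nrow(variant_table))) {
    ref <- variant_table$ref[j]
    alts <- variant_table$alts[[j]]
    m <- length(alts)
    cls <- classify_variant(ref, alts)
    pr <- upairs[, idx_mat[, j], drop = FALSE]
    codes <- matrix(NA_real_, nrow = n, ncol = m)
    for (t in seq_len(m)) {
      codes[, t] <- 1 - (pr[1, ] == t) - (pr[2, ] == t)
    }
    blocks[[j]] <- codes
    metas[[j]] <- tibble(
      column_id = paste(variant_table$chrom[j], variant_table$pos[j],
                        alts, sep = "_"),
      variant_id = variant_table$variant_id[j],
      chrom = variant_table$chrom[j],
      pos = variant_table$pos[j],
      ref = ref, alt = alts, alt_index = seq_len(m),
      column_class = cls$column_class
    )
  }
  data <- do.call(cbind, blocks)
  columns <- bind_rows(metas)
  colnames(data) <- columns$column_id
  rownames(data) <- individuals
  new_geno_matrix(data, columns, individuals)
}

new_geno_matrix <- function(data, columns, individuals) {
  nm <- colSums(!is.na(data))
  p_alt <- (2 * colSums(data == -1, na.rm = TRUE) +
              colSums(data == 0, na.rm = TRUE)) / (2 * pmax(nm, 1))
  columns$maf <- unname(pmin(p_alt, 1 - p_alt))
  columns$missing_frac <- unname(colSums(is.na(data)) / max(1, nrow(data)))
  structure(list(data = data, columns = columns, individuals = individuals),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d encoded columns\n",
              nrow(x$data), ncol(x$data)))
  cat("column classes:\n")
  print(table(x$columns$column_class))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$data)

#' Tidy per-column metadata of a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per encoded column (`column_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `column_class`, `maf`, `missing_frac`).
#' @export
tidy.geno_matrix <- function(x, ...) as_tibble(x$columns)

subset_geno_matrix <- function(gm, col_idx) {
  new_geno_matrix(gm$data[, col_idx, drop = FALSE],
                  gm$columns[col_idx, , drop = FALSE], gm$individuals)
}

#' Filter encoded columns on minor allele frequency and missingness
#'
#' Retains columns with minor allele frequency strictly above `maf_min` and
#' missing-data fraction strictly below `miss_max`. The MAF of a column is
#' computed on the collapsed pseudo-diploid codes over non-missing
#' individuals as `min(p, 1 - p)` with `p = (2 n_-1 + n_0) / (2 n_nonmissing)`.
#'
#' @param gm A `geno_matrix`.
#' @param maf_min MAF threshold (default 0.05, strict).
#' @param miss_max Missing-fraction threshold (default 0.20, strict).
#' @return A filtered `geno_matrix`.
#' @export
filter_columns <- function(gm, maf_min = 0.05, miss_max = 0.20) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (ncol(gm$data) == 0 || nrow(gm$data) == 0) {
    abort("empty genotype matrix", class = "polygp_degenerate_error")
  }
  keep <- which(gm$columns$maf > maf_min & gm$columns$missing_frac < miss_max)
  subset_geno_matrix(gm, keep)
}

#' Impute missing codes from each column's empirical distribution
#'
#' Each missing code is replaced by a draw from the empirical distribution of
#' the observed codes in the same column, preserving marginal code
#' frequencies. The draw is seeded so imputation is deterministic.
#'
#' @param gm A `geno_matrix` (typically after [filter_columns()]).
#' @param seed Integer seed.
#' @return A `geno_matrix` with no missing codes.
#' @export
impute_missing <- function(gm, seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"))
  data <- gm$data
  na_cols <- which(colSums(is.na(data)) > 0)
  if (length(na_cols)) {
    set.seed(stream_seed(seed, "impute"))
    for (j in na_cols) {
      obs <- data[!is.na(data[, j]), j]
      if (length(obs) == 0) {
        abort(sprintf("column %s is entirely missing; cannot impute",
                      colnames(data)[j]),
              class = "polygp_impute_error")
      }
      miss <- which(is.na(data[, j]))
      data[miss, j] <- sample(obs, length(miss), replace = TRUE)
    }
  }
  new_geno_matrix(data, gm$columns[, setdiff(names(gm$columns),
                                             c("maf", "missing_frac"))],
                  gm$individuals)
}
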