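#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file with GT fields of ploidy 2 or 4 (mixed ploidy within
#' one file is legal and resolved per individual). Multi-allelic records are
#' kept intact - never split into bi-allelic records - because the joint call
#' fixes the per-alternative-allele encoding; ALT order is preserved since it
#' fixes column order. Allele strings are kept verbatim, including the
#' spanning-deletion allele `*`. Any `.` component in a GT marks the call
#' missing.
#'
#' @param path Path to an (optionally gzipped) VCF file.
#' @return List with `variant_table` (tibble: `variant_id`, `chrom`, `pos`,
#'   `ref`, list-column `alts`, `var_class`), `calls` (individuals x loci
#'   character matrix of GT index strings, `NA` = missing) and `individuals`.
#' @export
read_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  pos <- as.integer(fix$POS)
  variant_table <- tibble(
    variant_id = paste(fix$CHROM, pos, sep = "_"),
    chrom = fix$CHROM, pos = pos, ref = fix$REF, alts = alts,
    var_class = vapply(seq_along(alts), function(j) {
      classify_variant(fix$REF[j], alts[[j]])$var_class
    }, character(1))
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  calls <- t(gt)
  bad <- !is.na(calls) & !grepl("^[0-9.]+([/|][0-9.]+){1,3}$", calls)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed GT '%s' at record %d (%s), individual %s",
                  calls[bad][1], w[2], variant_table$variant_id[w[2]],
                  rownames(calls)[w[1]]),
          class = "polygp_parse_error")
  }
  calls[grepl(".", calls, fixed = TRUE)] <- NA_character_
  colnames(calls) <- variant_table$variant_id
  list(variant_table = variant_table, calls = calls,
       individuals = rownames(calls))
}

#' Read gene intervals from a GFF3 file
#'
#' Keeps `gene` features only; coordinates are 1-based inclusive as in GFF3.
#' Features without an `ID` attribute are skipped with a warning; duplicate
#' gene ids are an error.
#'
#' @param path Path to a GFF3 file.
#' @return Annotation tibble: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = "ID"))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    warn("no gene features found in annotation")
    return(tibble(gene_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0)))
  }
  no_id <- is.na(genes$ID) | !nzchar(genes$ID)
  if (any(no_id)) {
    warn(sprintf("skipping %d gene feature(s) without an ID attribute",
                 sum(no_id)))
    genes <- genes[!no_id, , drop = FALSE]
  }
  if (anyDuplicated(genes$ID)) {
    abort("duplicate gene IDs in annotation", class = "polygp_parse_error")
  }
  tibble(gene_id = as.character(genes$ID), chrom = as.character(genes$seqid),
         start = as.integer(genes$start), end = as.integer(genes$end),
         strand = as.character(genes$strand))
}

#' Read a phenotype table
#'
#' Expects a tab-separated file whose header row starts with `individual`
#' followed by one column per trait; blank cells are missing values. The
#' decimal separator is always the point, independent of locale.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `individual` (character) and one numeric column per
#'   trait.
#' @export
read_phenotypes <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         locale = readr::locale(decimal_mark = "."),
                         progress = FALSE)
  names(raw)[1] <- "individual"
  if (anyDuplicated(raw$individual)) {
    abort(sprintf("duplicated individual ID: %s",
                  raw$individual[duplicated(raw$individual)][1]),
          class = "polygp_parse_error")
  }
  for (col in names(raw)[-1]) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- !is.na(vals) & nzchar(vals) & is.na(num)
    if (any(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                    vals[bad][1], col, which(bad)[1]),
            class = "polygp_parse_error")
    }
    raw[[col]] <- num
  }
  raw
}

#' Write a simulated panel to standard files
#'
#' Emits `panel.vcf` (VCF 4.2 genotypes; octoploid individuals carry 4 allele
#' indices per GT and missing calls are written `./.` or `./././.` according
#' to ploidy), `phenotypes.tsv`, `genes.gff3` and `causal_genes.txt` into
#' `directory`. Reading the files back through [read_genotypes()],
#' [read_phenotypes()] and [read_annotation()] reproduces the panel exactly
#' on genotype codes and coordinates.
#'
#' @param panel A `sim_panel` from [simulate_panel()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_panel <- function(panel, directory) {
  stopifnot(inherits(panel, "sim_panel"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, mode = 2) != 0) {
    abort(sprintf("cannot write to directory '%s'", directory),
          class = "polygp_io_error")
  }
  paths <- c(vcf = file.path(directory, "panel.vcf"),
             phenotypes = file.path(directory, "phenotypes.tsv"),
             gff3 = file.path(directory, "genes.gff3"),
             causal = file.path(directory, "causal_genes.txt"))

  vt <- panel$variant_table
  n <- nrow(panel$calls)
  ploidy <- panel$individuals$ploidy
  miss_gt <- ifelse(ploidy == 8L, "./././.", "./.")
  gt <- panel$calls
  for (i in seq_len(n)) gt[i, is.na(gt[i, ])] <- miss_gt[i]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polygp",
    sprintf("##contig=<ID=%s,length=%d>", unique(vt$chrom),
            as.integer(panel$config$genome_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(panel$calls)), collapse = "\t")
  )
  body <- paste(vt$chrom, vt$pos, vt$variant_id, vt$ref,
                vapply(vt$alts, paste, character(1), collapse = ","),
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), paths["vcf"])

  readr::write_tsv(panel$phenotypes, paths["phenotypes"], progress = FALSE)

  ann <- panel$annotation
  gff <- paste(ann$chrom, "polygp", "gene", ann$start, ann$end, ".",
               ann$strand, ".", paste0("ID=", ann$gene_id), sep = "\t")
  writeLines(c("##gff-version 3", gff), paths["gff3"])

  writeLines(panel$causal_genes, paths["causal"])
  invisible(paths)
}

#' Read a benchmark gene list (one gene id per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of gene ids (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
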