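#' Construct a genotype matrix object
#'
#' The central data container: an individuals-by-SNPs numeric matrix with
#' sample and SNP identifiers and optional population labels. Genotypes use
#' the 4-level integer coding 0 (homozygous wild-type), 1 (heterozygous),
#' 2 (homozygous variant-type), 3 (missing). Matrices whose values all lie in
#' \{0, 1, 2, 3\} are flagged `integer_coded`; imputation with the mean or
#' median produces fractional values and clears the flag.
#'
#' @param values numeric matrix, individuals in rows, SNPs in columns.
#' @param sample_ids character vector of unique row identifiers. Defaults to
#'   `rownames(values)`, or `ind1, ind2, ...` when absent.
#' @param snp_ids character vector of unique column identifiers. Defaults to
#'   `colnames(values)`, or `snp1, snp2, ...` when absent.
#' @param labels optional named character vector mapping every sample id to a
#'   population name, or `NULL`.
#' @return An object of class `genotype_matrix` with fields `values`,
#'   `sample_ids`, `snp_ids`, `labels` and `integer_coded`.
#' @export
genotype_matrix <- function(values, sample_ids = NULL, snp_ids = NULL,
                            labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_ncmce("parse", "genotype values must be numeric")
  }
  sample_ids <- sample_ids %||% rownames(values) %||%
    paste0("ind", seq_len(nrow(values)))
  snp_ids <- snp_ids %||% colnames(values) %||%
    paste0("snp", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(values)) {
    stop_ncmce("structure", "sample_ids length does not match row count")
  }
  if (length(snp_ids) != ncol(values)) {
    stop_ncmce("structure", "snp_ids length does not match column count")
  }
  if (anyDuplicated(sample_ids)) {
    stop_ncmce("identity", "duplicate sample ids: ",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(snp_ids)) {
    stop_ncmce("identity", "duplicate SNP ids: ",
               paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  obj <- structure(
    list(values = values, sample_ids = sample_ids, snp_ids = snp_ids,
         labels = NULL,
         integer_coded = all(values %in% c(0, 1, 2, 3))),
    class = "genotype_matrix"
  )
  if (!is.null(labels)) obj <- set_labels(obj, labels)
  obj
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$integer_coded) "integer 0/1/2/3 coding" else "numeric"))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("populations:", paste(sprintf("%s (%d)", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

set_labels <- function(g, labels) {
  labels <- labels[!is.na(labels)]
  missing_ids <- setdiff(g$sample_ids, names(labels))
  if (length(missing_ids) > 0) {
    stop_ncmce("labelling", "samples without a population label: ",
               paste(missing_ids, collapse = ", "))
  }
  extra <- setdiff(names(labels), g$sample_ids)
  if (length(extra) > 0) {
    warning("ignoring labels for unknown samples: ",
            paste(extra, collapse = ", "))
  }
  g$labels <- labels[g$sample_ids]
  g
}

#' Read a delimited genotype table
#'
#' Parses the package's primary on-disk format: a delimited text table with
#' one individual per row, the first column holding the sample id and the
#' remaining columns holding numeric genotype values. An optional header row
#' carries the SNP ids (with or without a leading name for the id column).
#'
#' @param path path to the table.
#' @param delimiter single-character field separator (default `","`).
#' @param has_header logical; whether the first line holds SNP ids.
#' @return A [genotype_matrix].
#' @export
read_genotype_table <- function(path, delimiter = ",", has_header = TRUE) {
  if (!file.exists(path)) stop_ncmce("io", "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_ncmce("structure", "empty genotype table: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  snp_ids <- NULL
  if (has_header) {
    header <- trimws(fields[[1]])
    fields <- fields[-1]
    if (length(fields) == 0) {
      stop_ncmce("structure", "genotype table has a header but no data rows")
    }
    n_fields <- length(fields[[1]])
    snp_ids <- if (length(header) == n_fields) header[-1] else header
    if (length(snp_ids) != n_fields - 1) {
      stop_ncmce("structure", "header has ", length(header),
                 " fields but data rows have ", n_fields)
    }
  }
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop_ncmce("structure", "ragged row ", bad, ": ", widths[bad],
               " fields, expected ", widths[1])
  }
  if (widths[1] < 2) stop_ncmce("structure", "rows need a sample id and at least one SNP")
  sample_ids <- vapply(fields, function(f) trimws(f[1]), character(1))
  n_snps <- widths[1] - 1
  values <- matrix(NA_real_, length(fields), n_snps)
  for (i in seq_along(fields)) {
    row <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1]
      stop_ncmce("parse", "non-numeric cell at row ", i, ", column ", j + 1,
                 ": '", trimws(fields[[i]][j + 1]), "'")
    }
    values[i, ] <- row
  }
  genotype_matrix(values, sample_ids = sample_ids, snp_ids = snp_ids)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: sample id in the first column, SNP ids
#' in the header. `read_genotype_table(write_genotype_table(g, f))` reproduces
#' values and identifiers exactly.
#'
#' @param g a [genotype_matrix].
#' @param path output file path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, delimiter = ",") {
  stopifnot(inherits(g, "genotype_matrix"))
  header <- paste(c("sample_id", g$snp_ids), collapse = delimiter)
  rows <- vapply(seq_along(g$sample_ids), function(i) {
    paste(c(g$sample_ids[i], format(g$values[i, ], trim = TRUE, digits = 17)),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Extracts the GT subfield of a VCF and recodes it to allele dosages:
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, any call with a missing
#' allele (`./.`, `.|1`, ...) `-> 3`. Phase separators (`|`) are ignored.
#' Only biallelic sites are kept; multiallelic records are skipped and their
#' count reported in a message.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return A [genotype_matrix] with individuals in rows and SNP ids of the
#'   form `CHROM:POS:REF:ALT`.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_ncmce("io", "reading VCF requires the vcfR package")
  }
  if (!file.exists(path)) stop_ncmce("io", "file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    stop_ncmce("format", "VCF records lack a GT format key")
  }
  biallelic <- vcfR::is.biallelic(vcf)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0) {
    message("skipped ", n_skipped, " non-biallelic record(s)")
    vcf <- vcf[biallelic, ]
  }
  if (nrow(vcf@fix) == 0) {
    stop_ncmce("structure", "no biallelic sites in VCF: ", path)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcf@fix
  snp_ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
                   sep = ":")
  code_gt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(3, length(x))
    out[x %in% "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% "1/1"] <- 2
    out
  }
  values <- matrix(code_gt(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt))
  genotype_matrix(t(values), sample_ids = colnames(gt), snp_ids = snp_ids)
}

#' Attach population labels from a two-column table
#'
#' @param g a [genotype_matrix].
#' @param table path to a delimited file with columns sample id, population
#'   name (no header).
#' @param delimiter field separator (default tab).
#' @return `g` with `labels` populated for every sample. Samples absent from
#'   the table raise an error naming them; table rows for unknown samples are
#'   ignored with a warning.
#' @export
attach_labels <- function(g, table, delimiter = "\t") {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!file.exists(table)) stop_ncmce("io", "file not found: ", table)
  df <- utils::read.table(table, sep = delimiter, header = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2) stop_ncmce("structure", "label table needs two columns")
  labels <- stats::setNames(df[[2]], df[[1]])
  set_labels(g, labels)
}
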