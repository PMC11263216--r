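# Reading, validating and writing GWAS summary statistics and pathway sets.

# Canonical internal schema; external header dialects are mapped onto this
# via `column_map`.
GWAS_COLUMNS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a summary-statistics dataset
#'
#' A `summary_dataset` holds one trait's per-SNP associations: alleles,
#' effect-allele frequency, beta (log-odds for binary traits, SD units for
#' quantitative ones), its standard error, p-value and sample size. Betas and
#' EAF are always interpreted relative to `effect_allele`; strand issues are
#' resolved later, during harmonization.
#'
#' @param records data.frame with columns `snp`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_id character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param validate drop rows violating the record invariants (with a logged
#'   count) before constructing the dataset.
#' @return an object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_id,
                            trait_type = c("quantitative", "binary"),
                            validate = TRUE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(GWAS_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[GWAS_COLUMNS]
  records$snp <- as.character(records$snp)
  records$chr <- as.character(records$chr)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (validate) records <- validate_records(records)
  if (nrow(records) == 0) stop("no valid association records for trait ", trait_id)
  if (anyDuplicated(records$snp)) {
    stop("duplicate snp ids in trait ", trait_id, ": ",
         paste(unique(records$snp[duplicated(records$snp)]), collapse = ", "))
  }
  rownames(records) <- NULL
  structure(list(trait_id = trait_id, trait_type = trait_type,
                 records = records),
            class = "summary_dataset")
}

# Enforce AssociationRecord invariants; invalid rows are dropped with a
# logged count. p vs z inconsistency only warns (published p-values are
# rounded), at a factor-2 tolerance on the -log10 scale.
validate_records <- function(records) {
  ok <- !is.na(records$snp) & nzchar(records$snp) &
    records$effect_allele %in% DNA_BASES &
    records$other_allele %in% DNA_BASES &
    records$effect_allele != records$other_allele &
    is.finite(records$eaf) & records$eaf > 0 & records$eaf < 1 &
    is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
    is.finite(records$n) & records$n > 0
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    message("Dropped ", sum(!ok), " of ", length(ok),
            " rows failing association-record validation")
  }
  kept <- records[ok, , drop = FALSE]
  if (nrow(kept) > 0) {
    expected <- -log10(pmax(z_pval(kept$beta / kept$se), .Machine$double.xmin))
    observed <- -log10(kept$pval)
    off <- abs(observed - expected) > log10(2) & expected < 300
    if (any(off)) {
      warning(sum(off), " row(s) have p-values inconsistent with beta/se ",
              "beyond factor 2 in -log10 (kept)", call. = FALSE)
    }
  }
  kept
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path path to a delimited text file with a header row.
#' @param trait_id trait label; defaults to the file name.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param column_map named character vector mapping canonical field names
#'   (`snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`) to the file's column names, for files using another
#'   header dialect.
#' @param sep field separator, tab by default.
#' @return a [summary_dataset()].
#' @export
read_summary <- function(path, trait_id = NULL,
                         trait_type = c("quantitative", "binary"),
                         column_map = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- stats::setNames(GWAS_COLUMNS, GWAS_COLUMNS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), GWAS_COLUMNS)
    if (length(bad) > 0) stop("unknown canonical field(s) in column_map: ",
                              paste(bad, collapse = ", "))
    wanted[names(column_map)] <- column_map
  }
  missing_cols <- wanted[!wanted %in% names(tab)]
  if (length(missing_cols) > 0) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  records <- stats::setNames(tab[unname(wanted)], names(wanted))
  summary_dataset(records, trait_id %||% basename(path), trait_type)
}

#' Write a summary dataset as tab-separated values
#'
#' Canonical column order, no quoting; `read_summary()` on the written file
#' reproduces the dataset field-for-field for exactly representable values.
#'
#' @param dataset a [summary_dataset()].
#' @param path output path.
#' @export
write_summary <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  if (nrow(dataset$records) == 0) stop("refusing to write an empty dataset")
  utils::write.table(dataset$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s): %d SNPs\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  invisible(x)
}

#' Number of SNP records in a dataset
#' @param dataset a [summary_dataset()].
#' @export
n_records <- function(dataset) nrow(dataset$records)

#' Read pathway sets from a GMT-style file
#'
#' One pathway per line: pathway id, display name, then member compound IDs,
#' tab-separated (comma accepted as a fallback separator). Duplicate members
#' within a line are deduplicated.
#'
#' @param path path to the pathway file.
#' @return list of `pathway_set` objects (fields `pathway_id`, `name`,
#'   `members`).
#' @export
read_pathways <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop("pathway line ", i, " has no members: ", lines[i])
    }
    structure(list(pathway_id = fields[1], name = fields[2],
                   members = unique(fields[-(1:2)])),
              class = "pathway_set")
  })
}
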