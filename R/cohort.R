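# Domain containers and readers for genotype / phenotype files.
#
# A cohort bundles the per-patient pieces the model needs: an N x P additive
# dosage matrix (0/1/2, NA = missing), an N x Q encoded covariate matrix,
# follow-up time and the event indicator.  All containers are row-aligned by
# patient id.

#' Assemble a cohort object
#'
#' Bundles genotypes, encoded covariates and the censored time-to-event
#' outcome into a validated, row-aligned container used by all downstream
#' functions.
#'
#' @param time nonnegative follow-up durations (unit is opaque; only the
#'   interval grid interprets it).
#' @param event per-patient indicator, 0 = censored, 1 = event.
#' @param genotypes optional N x P matrix of additive dosages in
#'   \{0, 1, 2, NA\}.
#' @param covariates optional N x Q numeric matrix of encoded clinical
#'   covariates.
#' @param patient_ids character ids; default "P1", "P2", ...
#' @param snp_ids,snp_chroms marker names and chromosome labels
#'   (length P) for the genotype columns.
#' @return an object of class `st_cohort`.
#' @export
make_cohort <- function(time, event, genotypes = NULL, covariates = NULL,
                        patient_ids = NULL, snp_ids = NULL, snp_chroms = NULL) {
  n <- length(time)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(n))
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != n || length(event) != n)
    stop("patient_ids, time and event must all have length N = ", n)
  if (any(!is.finite(time)) || any(time < 0))
    stop("time must be nonnegative and finite for every patient")
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event) for every patient")
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    if (nrow(genotypes) != n)
      stop("genotypes has ", nrow(genotypes), " rows but N = ", n)
    bad <- !(genotypes %in% c(0, 1, 2)) & !is.na(genotypes)
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(genotypes)), arr.ind = TRUE)[1, ]
      stop("genotype dosage outside {0,1,2,NA} at row ", idx[1],
           ", column ", idx[2])
    }
    if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
    if (length(snp_ids) != ncol(genotypes))
      stop("snp_ids length does not match the number of genotype columns")
    colnames(genotypes) <- snp_ids
    rownames(genotypes) <- patient_ids
    if (!is.null(snp_chroms) && length(snp_chroms) != ncol(genotypes))
      stop("snp_chroms length does not match the number of genotype columns")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates has ", nrow(covariates), " rows but N = ", n)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("V", seq_len(ncol(covariates)))
    rownames(covariates) <- patient_ids
  }
  structure(list(patient_ids = patient_ids,
                 genotypes = genotypes,
                 snp_ids = if (is.null(genotypes)) NULL else colnames(genotypes),
                 snp_chroms = if (is.null(snp_chroms)) NULL else as.character(snp_chroms),
                 covariates = covariates,
                 time = as.numeric(time),
                 event = as.integer(event)),
            class = "st_cohort")
}

#' @export
print.st_cohort <- function(x, ...) {
  cat("Censored time-to-event cohort (st_cohort)\n")
  cat("  patients:  ", length(x$patient_ids), "\n")
  cat("  events:    ", sum(x$event), sprintf(" (%.1f%%)", 100 * mean(x$event)), "\n")
  if (!is.null(x$genotypes))
    cat("  SNPs:      ", ncol(x$genotypes), " (",
        sum(is.na(x$genotypes)), " missing calls)\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates:", ncol(x$covariates), "-",
        paste(head(colnames(x$covariates), 6), collapse = ", "), "\n")
  invisible(x)
}

#' Read additive genotype dosages from a PLINK .raw file
#'
#' Parses the whitespace-delimited output of `plink --recode A`: six leading
#' columns (FID IID PAT MAT SEX PHENOTYPE) followed by one column per marker
#' holding dosages in \{0, 1, 2, NA\}.
#'
#' @param path file path.
#' @return list with `patient_ids`, `snp_ids` and the N x P `genotypes`
#'   matrix (NA where the file had NA); column order preserved.
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, na.strings = "NA",
                          data.table = FALSE, colClasses = list(character = 1:2))
  req <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(dt) < 6 || !identical(names(dt)[1:6], req)) {
    got <- names(dt)[seq_len(min(6, ncol(dt)))]
    off <- which(got != req[seq_along(got)])[1]
    stop("malformed .raw header: expected column ",
         if (is.na(off)) "layout FID IID PAT MAT SEX PHENOTYPE"
         else paste0(off, " to be '", req[off], "', found '", got[off], "'"))
  }
  geno <- as.matrix(dt[, -(1:6), drop = FALSE])
  if (ncol(geno) > 0) {
    storage.mode(geno) <- "numeric"
    bad <- !(geno %in% c(0, 1, 2)) & !is.na(geno)
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(geno)), arr.ind = TRUE)[1, ]
      stop("invalid dosage '", geno[idx[1], idx[2]], "' at row ", idx[1],
           ", column ", colnames(geno)[idx[2]], ": must be 0, 1, 2 or NA")
    }
  } else {
    geno <- matrix(numeric(0), nrow = nrow(dt), ncol = 0)
  }
  list(patient_ids = as.character(dt$IID),
       snp_ids = colnames(geno),
       genotypes = geno)
}

#' Write a dosage matrix as a PLINK .raw file
#'
#' Inverse of [read_plink_raw()]; pedigree columns are filled with
#' placeholders (PAT = MAT = SEX = 0, PHENOTYPE = -9).
#'
#' @param genotypes N x P dosage matrix, NA for missing.
#' @param path output path.
#' @param patient_ids ids written to FID and IID; default rownames.
#' @export
write_plink_raw <- function(genotypes, path, patient_ids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(nrow(genotypes)))
  snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  out <- data.frame(FID = patient_ids, IID = patient_ids, PAT = 0, MAT = 0,
                    SEX = 0, PHENOTYPE = -9, check.names = FALSE)
  out <- cbind(out, as.data.frame(genotypes))
  names(out) <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", snp_ids)
  data.table::fwrite(out, path, sep = " ", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read additive genotype dosages from a VCF
#'
#' Converts GT calls of biallelic records to additive ALT-allele dosages:
#' 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA.  Multiallelic records are
#' skipped with a warning and counted in `n_skipped`.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return list with `patient_ids`, `snp_ids`, `snp_chroms`, N x P
#'   `genotypes` and `n_skipped`.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) > 0 && !all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"])))
    stop("VCF format error: GT field missing from FORMAT")
  multi <- grepl(",", vcf@fix[, "ALT"], fixed = TRUE)
  n_skipped <- sum(multi)
  if (n_skipped > 0)
    warning("skipped ", n_skipped, " multiallelic record(s)")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- vcf@fix[!multi, , drop = FALSE]
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  gtn <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(map[gtn], nrow = nrow(gtn), ncol = ncol(gtn))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  geno <- t(dos)
  colnames(geno) <- ids
  rownames(geno) <- colnames(gt)
  list(patient_ids = colnames(gt), snp_ids = ids,
       snp_chroms = as.character(fix[, "CHROM"]),
       genotypes = geno, n_skipped = n_skipped)
}

# Dummy-encode the non-numeric columns of a covariate data.frame.  The most
# frequent level becomes the reference (ties broken by sort order) and is
# recorded so the encoding is reproducible.
encode_covariates <- function(df) {
  cols <- list()
  refs <- character(0)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      tab <- sort(table(v), decreasing = TRUE)
      ref <- names(tab)[1]
      refs[nm] <- ref
      for (lev in setdiff(sort(unique(v)), ref))
        cols[[paste0(nm, ".", lev)]] <- as.numeric(v == lev)
    }
  }
  m <- do.call(cbind, cols)
  if (is.null(m)) m <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  attr(m, "reference_levels") <- refs
  m
}

#' Read a phenotype / covariate table
#'
#' Reads a delimited table with one row per patient, validates the outcome
#' columns, and dummy-encodes categorical covariates (most frequent level as
#' reference, recorded in `attr(covariates, "reference_levels")`).
#'
#' @param path CSV/TSV file path (delimiter sniffed by `data.table::fread`).
#' @param id_col,time_col,event_col column names of the patient id,
#'   follow-up time, and 0/1 event indicator.
#' @param covariate_cols character vector of covariate columns; default all
#'   remaining columns.
#' @return list with `patient_ids`, `time`, `event` and the encoded
#'   `covariates` matrix.
#' @export
read_phenotypes <- function(path, id_col = "id", time_col = "time",
                            event_col = "event", covariate_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  for (cn in c(id_col, time_col, event_col))
    if (!cn %in% names(df)) stop("column '", cn, "' not found in ", path)
  time <- as.numeric(df[[time_col]])
  event <- df[[event_col]]
  if (any(!is.finite(time)) || any(time < 0))
    stop("negative or missing follow-up time in row ",
         which(!is.finite(time) | time < 0)[1])
  if (!all(event %in% c(0, 1)))
    stop("event indicator outside {0,1} in row ",
         which(!event %in% c(0, 1))[1])
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(df), c(id_col, time_col, event_col))
  covs <- encode_covariates(df[, covariate_cols, drop = FALSE])
  rownames(covs) <- as.character(df[[id_col]])
  list(patient_ids = as.character(df[[id_col]]),
       time = time, event = as.integer(event), covariates = covs)
}

#' Join genotype and phenotype parts into a cohort
#'
#' Matches patients across sources by string id equality (order-independent);
#' any id present in one source but not the other raises an alignment error
#' listing the unmatched ids.
#'
#' @param geno output of [read_plink_raw()] or [read_vcf_genotypes()].
#' @param pheno output of [read_phenotypes()].
#' @return an `st_cohort` ordered as the genotype source.
#' @export
join_cohort <- function(geno, pheno) {
  only_g <- setdiff(geno$patient_ids, pheno$patient_ids)
  only_p <- setdiff(pheno$patient_ids, geno$patient_ids)
  if (length(only_g) || length(only_p))
    stop("patient id mismatch between genotype and phenotype sources; ",
         "genotype-only: [", paste(only_g, collapse = ", "),
         "], phenotype-only: [", paste(only_p, collapse = ", "), "]")
  ord <- match(geno$patient_ids, pheno$patient_ids)
  make_cohort(time = pheno$time[ord], event = pheno$event[ord],
              genotypes = geno$genotypes,
              covariates = pheno$covariates[ord, , drop = FALSE],
              patient_ids = geno$patient_ids,
              snp_ids = geno$snp_ids, snp_chroms = geno$snp_chroms)
}
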