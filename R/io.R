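#' Read a pedigree CSV
#'
#' Expects a header with columns `id,sire,dam`; `"0"` denotes an unknown
#' parent.
#'
#' @param path File path.
#' @return A validated [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("id", "sire", "dam") %in% names(df))) {
    stop("malformed pedigree file '", path,
         "': header must contain id,sire,dam", call. = FALSE)
  }
  as_pedigree(df)
}

#' Write a pedigree CSV
#' @param pedigree A pedigree object.
#' @param path Output path; unknown parents are written as `"0"`.
#' @export
write_pedigree <- function(pedigree, path) {
  ped <- tibble::as_tibble(pedigree)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  readr::write_csv(ped, path)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Columns: `id`, the trait, then any fixed-effect / covariate columns.
#' Declared factor columns are converted to factors.
#'
#' @param path File path.
#' @param factors Character vector of factor column names.
#' @return Tibble of records.
#' @export
read_phenotypes <- function(path, factors = character()) {
  df <- readr::read_csv(path, col_types = readr::cols(id = "c"),
                        show_col_types = FALSE)
  if (!"id" %in% names(df)) {
    stop("malformed phenotype file '", path, "': no id column", call. = FALSE)
  }
  missing_fac <- setdiff(factors, names(df))
  if (length(missing_fac) > 0) {
    stop("declared factor column(s) absent: ",
         paste(missing_fac, collapse = ", "), call. = FALSE)
  }
  for (f in factors) df[[f]] <- factor(df[[f]])
  df
}

#' Write phenotypes to CSV
#' @param phenotypes Record table.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(tibble::as_tibble(phenotypes), path)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' Two dialects: `"tsv"` (header of locus ids, first column the individual
#' id, dosages 0/1/2 with `NA` for missing) and `"raw"` (PLINK `.raw`:
#' whitespace-separated, columns FID IID PAT MAT SEX PHENOTYPE then one
#' column per SNP; only IID and the dosages are used).
#'
#' @param path File path.
#' @param format `"tsv"` or `"raw"`.
#' @return Numeric matrix with individual ids as rownames.
#' @export
read_genotypes <- function(path, format = c("tsv", "raw")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "d",
                                                        id = "c"),
                          show_col_types = FALSE)
    if (!"id" %in% names(df)) {
      stop("malformed genotype file '", path, "': no id column",
           call. = FALSE)
    }
    M <- as.matrix(df[setdiff(names(df), "id")])
    rownames(M) <- df$id
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df))) {
      stop("malformed .raw file '", path, "': missing PLINK header columns",
           call. = FALSE)
    }
    M <- as.matrix(df[setdiff(names(df), meta)])
    rownames(M) <- as.character(df$IID)
  }
  bad <- M[!is.na(M) & !(M %in% c(0, 1, 2))]
  if (length(bad) > 0) {
    stop("genotype dosages must be 0/1/2 or NA; found e.g. ", bad[1],
         call. = FALSE)
  }
  M
}

#' Write a genotype dosage matrix as TSV
#' @param genotypes Dosage matrix with id rownames.
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- tibble::as_tibble(genotypes, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write / read a labelled square matrix as TSV
#' @param m Matrix with id dimnames.
#' @param path File path.
#' @export
write_matrix <- function(m, path) {
  readr::write_tsv(tibble::as_tibble(m, rownames = "id"), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(id = "c",
                                                      .default = "d"),
                        show_col_types = FALSE)
  m <- as.matrix(df[setdiff(names(df), "id")])
  rownames(m) <- df$id
  m
}

#' Read a partial/whole EBV pair table
#'
#' TSV with columns `id`, `ebv_partial`, `ebv_whole` and optionally `subset`
#' (`r`/`v`/`all` or `reference`/`validation`).
#'
#' @param path File path.
#' @return Tibble ready for [lr_stats()].
#' @export
read_ebv_pair <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(id = "c"),
                        show_col_types = FALSE)
  need <- setdiff(c("id", "ebv_partial", "ebv_whole"), names(df))
  if (length(need) > 0) {
    stop("malformed EBV pair file '", path, "': missing ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if ("subset" %in% names(df)) {
    df$subset <- dplyr::recode(df$subset, r = "reference", v = "validation")
  }
  df
}

#' Serialize an evaluation to a directory
#'
#' Writes `solutions.tsv` (id, ebv, pev), the `C_uu.tsv` / `C_bb.tsv`
#' matrices when present, and `meta.json` (variance components, tags,
#' package version).
#'
#' @param fit A [solve_mme()] fit.
#' @param dir Output directory (created if needed).
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(fit, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory '", dir, "' is not empty; use force = TRUE",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sol <- tibble::tibble(id = names(fit$u), ebv = unname(fit$u))
  if (!is.null(fit$C_uu)) sol$pev <- diag(fit$C_uu)
  readr::write_tsv(sol, file.path(dir, "solutions.tsv"))
  readr::write_tsv(tibble::tibble(term = names(fit$beta),
                                  estimate = unname(fit$beta)),
                   file.path(dir, "fixed_effects.tsv"))
  if (!is.null(fit$C_uu)) write_matrix(fit$C_uu, file.path(dir, "C_uu.tsv"))
  if (!is.null(fit$C_bb)) write_matrix(fit$C_bb, file.path(dir, "C_bb.tsv"))
  meta <- list(model = fit$model, data_tag = fit$data_tag, n_records = fit$n,
               vc = unclass(fit$vc),
               package_version = as.character(utils::packageVersion("lrcv")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write an LR report (statistics + expectations)
#'
#' @param stats Tibble from [lr_stats()].
#' @param dir Output directory.
#' @param expectations Optional tibble from [lr_expectations()].
#' @param force Overwrite existing files.
#' @return `dir`, invisibly.
#' @export
write_lr_report <- function(stats, dir, expectations = NULL, force = FALSE) {
  if (dir.exists(dir) && file.exists(file.path(dir, "lr_stats.tsv")) &&
      !force) {
    stop("report already exists in '", dir, "'; use force = TRUE",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(stats, file.path(dir, "lr_stats.tsv"))
  report <- list(statistics = stats)
  if (!is.null(expectations)) {
    readr::write_tsv(expectations, file.path(dir, "lr_expectations.tsv"))
    report$expectations <- expectations
  }
  jsonlite::write_json(report, file.path(dir, "lr_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write a simulated population to a dataset directory
#'
#' Emits the same formats the readers consume: `pedigree.csv`,
#' `phenotypes.csv`, `truth.tsv`, optionally `genotypes.tsv`, plus
#' `config.json` with the resolved configuration and seed.
#'
#' @param pop A [simulate_population()] result.
#' @param dir Output directory.
#' @param force Overwrite existing files.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir, force = FALSE) {
  stopifnot(inherits(pop, "sim_population"))
  if (dir.exists(dir) && file.exists(file.path(dir, "pedigree.csv")) &&
      !force) {
    stop("dataset already exists in '", dir, "'; use force = TRUE",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(pop$pedigree, file.path(dir, "pedigree.csv"))
  write_phenotypes(pop$phenotypes, file.path(dir, "phenotypes.csv"))
  readr::write_tsv(pop$truth, file.path(dir, "truth.tsv"))
  if (!is.null(pop$genotypes)) {
    write_genotypes(pop$genotypes, file.path(dir, "genotypes.tsv"))
  }
  cfg <- unclass(pop$config)
  cfg$seed <- pop$seed
  cfg$package_version <- as.character(utils::packageVersion("lrcv"))
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
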