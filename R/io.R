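# Tab-separated readers/writers for the pipeline's on-disk interchange
# formats. All tabular outputs are TSV with a header row; file-level
# metadata travels in leading '#'-prefixed comment lines.

write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a cohort table
#'
#' One row per individual: `event` (0/1), `age` (years), `sex`, `array`,
#' PC columns `PC1..`, optional cardiometabolic columns.
#'
#' @param cohort cohort data.frame.
#' @param path file path (tab-separated, header row).
#' @export
write_cohort_table <- function(cohort, path) {
  write_tsv(cohort, path, meta = list(schema = "fluxamp cohort v1"))
}

#' @rdname write_cohort_table
#' @return `read_cohort_table`: the validated cohort data.frame.
#' @export
read_cohort_table <- function(path) {
  df <- read_tsv(path)
  need <- c("event", "age", "sex", "array")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$event %in% c(0, 1)))
    stop("cohort table '", path, "': column 'event' must be 0/1")
  if (any(df$age <= 0))
    stop("cohort table '", path, "': column 'age' must be positive")
  df
}

#' Write / read a genotype dosage matrix
#'
#' Individuals x SNPs, dosages in \[0, 2\], SNP names as the header.
#'
#' @param genotypes dosage matrix.
#' @param path file path.
#' @export
write_genotype_dosages <- function(genotypes, path) {
  write_tsv(as.data.frame(genotypes), path,
            meta = list(schema = "fluxamp dosages v1"))
}

#' @rdname write_genotype_dosages
#' @return `read_genotype_dosages`: the dosage matrix.
#' @export
read_genotype_dosages <- function(path) {
  df <- read_tsv(path)
  g <- as.matrix(df)
  if (any(g < 0 | g > 2, na.rm = TRUE))
    stop("genotype file '", path, "': dosages outside [0, 2]")
  attr(g, "maf") <- colMeans(g) / 2
  g
}

#' Write / read a flux matrix with organ labels
#'
#' Individuals x reactions; organ labels are stored in per-reaction
#' comment lines (`# organ <reaction> <organ>`) ahead of the header.
#'
#' @param fluxes flux matrix with organ attribute (see [flux_organs()]).
#' @param path file path.
#' @export
write_flux_matrix <- function(fluxes, path) {
  organs <- flux_organs(fluxes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema: fluxamp fluxes v1", con)
  if (!is.null(organs))
    writeLines(paste("# organ", names(organs), organs, sep = "\t"), con)
  utils::write.table(as.data.frame(fluxes), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname write_flux_matrix
#' @return `read_flux_matrix`: the flux matrix with organ attribute
#'   restored.
#' @export
read_flux_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  organ_lines <- grep("^# organ\t", meta, value = TRUE)
  f <- as.matrix(read_tsv(path))
  if (length(organ_lines)) {
    parts <- strsplit(sub("^# organ\t", "", organ_lines), "\t")
    organs <- stats::setNames(vapply(parts, `[`, "", 2),
                              vapply(parts, `[`, "", 1))
    miss <- setdiff(colnames(f), names(organs))
    if (length(miss))
      stop("flux file '", path, "' lacks organ label for: ",
           paste(miss, collapse = ", "))
    attr(f, "organ") <- organs[colnames(f)]
  }
  f
}

#' Write simulation ground truth as a key-value text file
#'
#' @param truth `sim_truth` from [simulate_survival()].
#' @param path file path.
#' @export
write_sim_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("seed\t", truth$seed), con)
  writeLines(paste0("censor_age\t", truth$censor_age), con)
  writeLines(paste0("baseline_shape\t",
                    paste(truth$baseline$shape, collapse = ",")), con)
  writeLines(paste0("baseline_scale\t",
                    paste(truth$baseline$scale, collapse = ",")), con)
  if (!is.null(truth$true_effects))
    for (i in seq_len(nrow(truth$true_effects))) {
      e <- truth$true_effects[i, ]
      writeLines(paste("effect", e$snp, e$reaction, e$beta_snp, e$beta_flux,
                       e$beta_snp2, e$beta_flux2, e$beta_interaction,
                       sep = "\t"), con)
    }
  if (!is.null(truth$eqtl_effects))
    for (i in seq_len(nrow(truth$eqtl_effects))) {
      e <- truth$eqtl_effects[i, ]
      writeLines(paste("eqtl", e$snp, e$reaction, e$effect, sep = "\t"), con)
    }
  invisible(path)
}
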