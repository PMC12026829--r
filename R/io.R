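# Plain-text readers and writers for every pipeline artifact.
#
# Markers: CSV, lines as rows, first column `line_id`, remaining columns one
# per marker. Phenotypes: two-column CSV (line_id, value); missing values
# mark prediction-only lines. GRM: CSV with line IDs as both header and
# first column. All joins are by exact string line ID; row order never
# matters.

#' Write a marker dosage matrix to CSV
#'
#' @param markers Dosage matrix with line IDs as rownames.
#' @param path Output file path.
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(line_id = rownames(markers), markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker dosage matrix
#'
#' @param path Input file.
#' @param format `"csv"` (the dialect of [write_markers()]) or `"vcf"`
#'   (GT fields converted to 0/1/2 dosages; multi-allelic records dropped
#'   with a message; missing genotypes mean-imputed). VCF support requires
#'   the vcfR package.
#' @return Dosage matrix with line IDs as rownames.
#' @export
read_markers <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") read_markers_csv(path) else read_markers_vcf(path)
}

read_markers_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse marker CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L || names(df)[1] != "line_id") {
    stop("marker CSV must have a `line_id` column followed by marker columns",
         call. = FALSE)
  }
  ids <- as.character(df$line_id)
  if (anyDuplicated(ids)) {
    stop("duplicate line IDs in marker file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

read_markers_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt) & !is.na(alt)
  n_drop <- sum(!biallelic)
  if (n_drop > 0) {
    message(sprintf("dropped %d multi-allelic record(s)", n_drop))
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  D <- apply(gt, 2, count_alt)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1, dimnames = list(NULL, names(D)))
  X <- t(D)  # samples x markers
  ids <- colnames(gt)
  marker_ids <- rownames(gt)
  dimnames(X) <- list(ids, marker_ids)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}

#' Write phenotypes to a two-column CSV
#'
#' @param phenotypes Named numeric vector (NA marks unobserved lines).
#' @param path Output file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(line_id = names(phenotypes), value = unname(phenotypes),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read phenotypes and align them to a set of line IDs
#'
#' @param path Two-column CSV (`line_id`, `value`).
#' @param line_ids Optional authority set of IDs (typically the marker
#'   rownames): phenotypes for unknown IDs raise an error; lines without a
#'   phenotype become NA (prediction-only).
#' @return Named numeric vector.
#' @export
read_phenotypes <- function(path, line_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("phenotype CSV must have columns line_id, value", call. = FALSE)
  }
  y <- stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  if (is.null(line_ids)) return(y)
  unknown <- setdiff(names(y), line_ids)
  if (length(unknown) > 0) {
    stop("phenotypes given for line ID(s) absent from the markers: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(rep(NA_real_, length(line_ids)), line_ids)
  out[names(y)] <- y
  out
}

#' Write / read a genomic relationship matrix
#'
#' CSV with line IDs as both the header and the first column.
#'
#' @param grm A [compute_grm()] result.
#' @param path File path.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(line_id = grm$line_ids, grm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("line_id", grm$line_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @param epsilon Regularization constant recorded on the reloaded object.
#' @export
read_grm <- function(path, epsilon = 1e-6) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, line_ids = ids,
                 regularization_epsilon = epsilon,
                 allele_freqs = NULL, n_markers_used = NA_integer_),
            class = "gblupqm_grm")
}

#' Serialize / restore a quantile-mapping transfer function
#'
#' Two-column CSV of knot pairs with a comment header carrying the knot
#' count and extrapolation policy.
#'
#' @param tf A [build_transfer()] result.
#' @param path File path.
#' @export
write_transfer <- function(tf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_knots=%d policy=%s", tf$n_knots,
                     tf$extrapolation_policy), con)
  utils::write.csv(data.frame(x_quantile = tf$x_quantiles,
                              y_quantile = tf$y_quantiles),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transfer
#' @export
read_transfer <- function(path) {
  header <- readLines(path, n = 1L)
  policy <- sub(".*policy=([a-z_]+).*", "\\1", header)
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(x_quantiles = df$x_quantile, y_quantiles = df$y_quantile,
                 n_knots = nrow(df), extrapolation_policy = policy),
            class = "qm_transfer")
}

#' Write an outlier report to CSV
#'
#' One row per scored line: base p-values, combined statistic and p-value,
#' flagged status, method and threshold.
#'
#' @param report A [flag_outliers()] result.
#' @param combined The `combined_outlier_result` it was built from.
#' @param base_p The base p-value matrix.
#' @param path File path.
#' @export
write_outlier_report <- function(report, combined, base_p, path) {
  ids <- rownames(base_p)
  df <- data.frame(line_id = ids, base_p,
                   statistic = combined$statistic[ids],
                   combined_p = combined$combined_p[ids],
                   flagged = ids %in% report$flagged_ids,
                   method = report$method, alpha = report$alpha,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write evaluation results
#'
#' Long-format CSV of fold rows plus a wide per-variant summary CSV
#' (variant x metric).
#'
#' @param table An `evaluation_table`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths of the two files written.
#' @export
write_evaluation <- function(table, dir, prefix = "evaluation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long_path <- file.path(dir, paste0(prefix, "_folds.csv"))
  wide_path <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(table$folds, long_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(table$summary, wide_path, row.names = FALSE, quote = FALSE)
  c(folds = long_path, summary = wide_path)
}

#' Write a GBLUP fit summary
#'
#' Flat JSON with the variance components and settings, plus a predictions
#' CSV (line ID, observed when present, predicted).
#'
#' @param fit A `gblup_fit`.
#' @param phenotypes Named numeric vector of observed values (NA allowed).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_fit_summary <- function(fit, phenotypes, dir, prefix = "gblup") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, paste0(prefix, "_fit.json"))
  jsonlite::write_json(
    list(mu_hat = fit$mu_hat, sigma_g2 = fit$sigma_g2,
         sigma_e2 = fit$sigma_e2, heritability = heritability(fit),
         method = fit$method, n_train = length(fit$train_ids),
         n_test = length(fit$test_ids),
         mcmc_diagnostics = fit$mcmc_diagnostics),
    json_path, auto_unbox = TRUE, digits = NA)
  ids <- names(fit$predictions)
  pred_path <- file.path(dir, paste0(prefix, "_predictions.csv"))
  utils::write.csv(
    data.frame(line_id = ids,
               observed = unname(phenotypes[ids]),
               predicted = unname(fit$predictions),
               stringsAsFactors = FALSE),
    pred_path, row.names = FALSE, quote = FALSE)
  c(fit = json_path, predictions = pred_path)
}
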