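#' Read a trajectory table
#'
#' Two dialects are supported. The wide dialect has one row per gene: first
#' column `gene_id`, remaining column names the pseudotime values
#' (strictly increasing). The long dialect has columns `gene_id`, `t`, `x`
#' (and optionally `branch`). Values below the [EXPR_CLAMP] floor are clamped
#' upward with a warning reporting the count; a non-monotone pseudotime
#' header or ragged/missing values are hard errors.
#'
#' @param path CSV or TSV file (by extension).
#' @param format `"wide"` or `"long"`.
#' @param branch Branch label attached to wide-format tables.
#' @return A long tibble `gene_id`, `branch`, `t`, `x`.
#' @examples
#' read_trajectories(system.file("extdata", "example_trajectories.csv",
#'                               package = "genecircuit"))
#' @export
read_trajectories <- function(path, format = c("wide", "long"),
                              branch = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (format == "wide") {
    if (names(tab)[1] != "gene_id") {
      stop("wide trajectory file must have 'gene_id' as its first column",
           call. = FALSE)
    }
    tvals <- suppressWarnings(as.numeric(names(tab)[-1]))
    if (anyNA(tvals)) stop("non-numeric pseudotime header", call. = FALSE)
    if (any(diff(tvals) <= 0)) {
      stop("pseudotime header must be strictly increasing", call. = FALSE)
    }
    ragged <- which(!stats::complete.cases(tab))
    if (length(ragged)) {
      stop("missing values in row(s): ", paste(ragged, collapse = ", "),
           call. = FALSE)
    }
    out <- tab |>
      tidyr::pivot_longer(-"gene_id", names_to = "t", values_to = "x") |>
      dplyr::mutate(t = as.numeric(.data$t), branch = branch, .after = 1) |>
      dplyr::arrange(.data$gene_id, .data$t)
  } else {
    need <- c("gene_id", "t", "x")
    if (!all(need %in% names(tab))) {
      stop("long trajectory file needs columns gene_id, t, x", call. = FALSE)
    }
    if (anyNA(tab$t) || anyNA(tab$x)) stop("missing t/x values", call. = FALSE)
    if (!"branch" %in% names(tab)) tab$branch <- branch
    out <- tab |>
      dplyr::select("gene_id", "branch", "t", "x") |>
      dplyr::arrange(.data$gene_id, .data$t)
    bad <- out |>
      dplyr::group_by(.data$gene_id, .data$branch) |>
      dplyr::summarise(ok = all(diff(.data$t) > 0), .groups = "drop")
    if (any(!bad$ok)) {
      stop("pseudotime not strictly increasing for gene(s): ",
           paste(bad$gene_id[!bad$ok], collapse = ", "), call. = FALSE)
    }
  }
  n_clamped <- sum(out$x < EXPR_CLAMP)
  if (n_clamped > 0) {
    warning(n_clamped, " value(s) below ", EXPR_CLAMP, " clamped upward",
            call. = FALSE)
    out$x <- clamp_expr(out$x)
  }
  tibble::as_tibble(out)
}

#' Write a trajectory table
#'
#' @param trajectories Long tibble `gene_id`, (`branch`,) `t`, `x`.
#' @param path Output CSV/TSV path (delimiter by extension).
#' @param format `"wide"` (genes x pseudotime header) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path,
                               format = c("wide", "long")) {
  format <- match.arg(format)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  if (format == "wide") {
    wide <- trajectories |>
      dplyr::select("gene_id", "t", "x") |>
      tidyr::pivot_wider(names_from = "t", values_from = "x")
    readr::write_delim(wide, path, delim = delim)
  } else {
    readr::write_delim(trajectories, path, delim = delim)
  }
  invisible(path)
}

#' Remove low-expressed genes from a trajectory table
#'
#' Mirrors the pre-fit filter of pseudotime pipelines: a gene is kept when
#' its mean normalized expression reaches `min_mean` and at least
#' `min_frac_above_clamp` of its points lie strictly above the clamp floor.
#'
#' @param trajectories Long tibble `gene_id`, `t`, `x`.
#' @param min_mean Minimum mean expression (default 0.1).
#' @param min_frac_above_clamp Minimum fraction of points above [EXPR_CLAMP]
#'   (default 0.1).
#' @param verbose Report kept/removed counts.
#' @return The filtered tibble (same columns).
#' @examples
#' tr <- tibble::tibble(gene_id = rep(c("on", "off"), each = 3),
#'                      t = rep(c(0, 0.5, 1), 2),
#'                      x = c(0.5, 0.6, 0.7, 1e-4, 1e-4, 1e-4))
#' filter_low_expressed(tr)
#' @export
filter_low_expressed <- function(trajectories, min_mean = 0.1,
                                 min_frac_above_clamp = 0.1,
                                 verbose = TRUE) {
  stopifnot(min_mean >= 0, min_frac_above_clamp >= 0)
  keep <- trajectories |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      ok = mean(.data$x) >= min_mean &&
        mean(.data$x > EXPR_CLAMP) >= min_frac_above_clamp,
      .groups = "drop")
  out <- dplyr::semi_join(trajectories, dplyr::filter(keep, .data$ok),
                          by = "gene_id")
  if (verbose) {
    message("filter_low_expressed: kept ", sum(keep$ok), "/", nrow(keep),
            " genes")
  }
  if (nrow(out) == 0) warning("no genes passed the filter", call. = FALSE)
  out
}

#' Read an estimation/screening configuration file
#'
#' Accepts YAML or JSON with any subset of the [fit_config()] fields plus the
#' stability settings `error_threshold`, `x_hi`, `bifurcation_decades`,
#' `bifurcation_points`. Unknown keys are an error (naming the key), so
#' typos do not silently fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `fit` (a [fit_config()]) and `stability`
#'   (a named list).
#' @examples
#' read_run_config(system.file("extdata", "example_config.yaml",
#'                             package = "genecircuit"))$fit$n_starts
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fit_keys <- c("n_starts", "seed", "lambda_penalty", "near_opt_tolerance",
                "error_threshold", "max_eval", "spline_df", "bounds")
  stab_keys <- c("error_threshold", "x_hi", "bifurcation_decades",
                 "bifurcation_points")
  unknown <- setdiff(names(raw), union(fit_keys, stab_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fit_args <- raw[intersect(names(raw), fit_keys)]
  if (!is.null(fit_args$bounds)) {
    fit_args$bounds <- utils::modifyList(default_bounds(),
                                         lapply(fit_args$bounds, as.numeric))
  }
  cfg <- do.call(fit_config, fit_args)
  stability <- raw[intersect(names(raw), stab_keys)]
  list(fit = cfg, stability = stability)
}

#' Read raw sparse counts plus per-cell pseudotime
#'
#' Optional entry point for unsmoothed data: a MatrixMarket counts matrix
#' (genes x cells) with gene and barcode sidecar files, and a per-cell
#' pseudotime CSV (`barcode`, `t`). Counts are library-size normalized to
#' the median depth and log1p-transformed — the standard normalization for
#' log-normalized single-cell expression — then returned as per-cell long
#' observations suitable for [resmooth_at_npc()].
#'
#' @param mtx_path MatrixMarket file (genes in rows).
#' @param genes_path One gene id per line.
#' @param barcodes_path One cell barcode per line.
#' @param pseudotime_path CSV with columns `barcode`, `t`.
#' @return A long tibble `gene_id`, `t`, `x` sorted by gene and pseudotime.
#' @export
read_raw_counts <- function(mtx_path, genes_path, barcodes_path,
                            pseudotime_path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required to read MTX files", call. = FALSE)
  }
  m <- Matrix::readMM(mtx_path)
  genes <- readr::read_lines(genes_path)
  barcodes <- readr::read_lines(barcodes_path)
  stopifnot(nrow(m) == length(genes), ncol(m) == length(barcodes))
  pt <- readr::read_csv(pseudotime_path, show_col_types = FALSE,
                        progress = FALSE)
  stopifnot(all(c("barcode", "t") %in% names(pt)))
  idx <- match(pt$barcode, barcodes)
  if (anyNA(idx)) stop("pseudotime table contains unknown barcodes",
                       call. = FALSE)
  m <- as.matrix(m[, idx, drop = FALSE])
  depth <- pmax(colSums(m), 1)
  norm <- log1p(t(t(m) / depth * median(depth)))
  tibble::tibble(
    gene_id = rep(genes, times = length(idx)),
    t = rep(pt$t, each = length(genes)),
    x = clamp_expr(as.vector(norm))
  ) |>
    dplyr::arrange(.data$gene_id, .data$t)
}

#' Write a synthetic dataset in raw sparse-count form
#'
#' Emulation of the raw-matrix inputs, mainly to exercise
#' [read_raw_counts()]: per-cell expression values are scaled and Poisson
#' sampled into a sparse genes x cells MatrixMarket file with gene/barcode
#' sidecars and a per-cell pseudotime CSV.
#'
#' @param cells Long tibble `gene_id`, `t`, `x` (e.g. from
#'   [generate_cell_data()]).
#' @param dir Output directory (created if needed).
#' @param depth_scale Counts per unit expression (default 100).
#' @return The directory, invisibly; files `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `pseudotime.csv`.
#' @export
write_raw_counts <- function(cells, dir, depth_scale = 100) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required to write MTX files", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sort(unique(cells$gene_id))
  key <- cells |>
    dplyr::distinct(.data$t) |>
    dplyr::arrange(.data$t) |>
    dplyr::mutate(barcode = sprintf("cell%05d", dplyr::row_number()))
  cells2 <- dplyr::left_join(cells, key, by = "t")
  counts <- stats::rpois(nrow(cells2), lambda = expm1(cells2$x) * depth_scale)
  m <- Matrix::sparseMatrix(
    i = match(cells2$gene_id, genes),
    j = match(cells2$barcode, key$barcode),
    x = counts, dims = c(length(genes), nrow(key))
  )
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_lines(genes, file.path(dir, "genes.tsv"))
  readr::write_lines(key$barcode, file.path(dir, "barcodes.tsv"))
  readr::write_csv(key[, c("barcode", "t")], file.path(dir, "pseudotime.csv"))
  invisible(dir)
}
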