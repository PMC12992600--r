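#' Read a plain-text key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored.  Values are converted to numeric where possible.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, function(p) trimws(p[1]), character(1)))
}

default_config <- function() {
  list(method = "lle", tau = 0.5, alpha = 0.01, k_min = 3, k_max = 100,
       tol = 1e-3, max_iter = 50, d_proj = NA, n_clusters = NA,
       n_epochs = 500, seed = 1, input = NA, labels = NA, out_dir = ".")
}

#' Run the adaptive embedding pipeline end to end
#'
#' Reads a data matrix (and optional labels), dispatches on
#' `config$method` (`"fit-id"`, `"lle"`, `"spectral"`, `"umap"`), and
#' writes the artifact bundle to `config$out_dir`: the embedding
#' (`embedding.csv`), the per-point neighbourhood sizes (`kstar.txt`),
#' the dimension report (`id_report.json`), clustering metrics
#' (`metrics.json`, when labels are available), and a reproducibility
#' manifest (`manifest.json`) with the full configuration, seed and
#' package version.  When no label file is given the metric stage is
#' skipped with a notice and the embedding is still written.
#'
#' @param config named list (see [read_config()]) or path to a config
#'   file.  Recognised keys: `input`, `labels`, `method`, `out_dir`,
#'   `tau`, `alpha`, `k_min`, `k_max`, `tol`, `max_iter`, `d_proj`,
#'   `n_clusters`, `n_epochs`, `seed`.
#' @return (invisibly) a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- modifyList(default_config(), config)
  ok_methods <- c("fit-id", "lle", "spectral", "umap")
  if (!cfg$method %in% ok_methods)
    stop("unknown method '", cfg$method, "'; valid methods: ",
         paste(ok_methods, collapse = ", "))
  if (is.na(cfg$input)) stop("config requires an 'input' matrix path")
  X <- read_matrix(cfg$input)
  labels <- NULL
  if (!is.na(cfg$labels) && nzchar(cfg$labels)) {
    labels <- scan(cfg$labels, what = integer(), quiet = TRUE)
  } else {
    message("no label file given; metrics stage skipped")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  set.seed(seed)
  k_max <- min(as.integer(cfg$k_max), nrow(X) - 1L)
  d_proj <- if (is.na(cfg$d_proj)) NULL else as.integer(cfg$d_proj)
  common <- list(tau = cfg$tau, alpha = cfg$alpha,
                 k_min = as.integer(cfg$k_min), k_max = k_max,
                 tol = cfg$tol, max_iter = as.integer(cfg$max_iter))

  fitted <- switch(cfg$method,
    `fit-id` = do.call(abide, c(list(X), common)),
    lle = do.call(lle_star, c(list(X, d_proj = d_proj), common)),
    spectral = {
      g <- if (!is.na(cfg$n_clusters)) as.integer(cfg$n_clusters)
           else length(unique(labels))
      if (!length(g) || is.na(g) || g < 2L)
        stop("spectral method needs n_clusters or a label file")
      do.call(sc_star, c(list(X, n_clusters = g, d_proj = d_proj,
                              seed = seed), common))
    },
    umap = do.call(umap_star,
                   c(list(X, d_proj = d_proj,
                          n_epochs = as.integer(cfg$n_epochs),
                          seed = seed), common)))

  est <- if (cfg$method == "fit-id") fitted$estimate else fitted$estimate
  K <- fitted$neighborhood
  paths <- list()
  paths$kstar <- file.path(cfg$out_dir, "kstar.txt")
  write.table(K$k_star, paths$kstar, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(est)) {
    paths$id_report <- file.path(cfg$out_dir, "id_report.json")
    jsonlite::write_json(
      list(d_hat = est$d_hat, d_star = est$d_star, std = est$std,
           converged = est$converged, iterations = est$iterations),
      paths$id_report, auto_unbox = TRUE, digits = NA)
  }
  if (cfg$method != "fit-id") {
    emb <- fitted$embedding
    paths$embedding <- file.path(cfg$out_dir, "embedding.csv")
    colnames(emb$Y) <- paste0("Y", seq_len(ncol(emb$Y)))
    write.table(emb$Y, paths$embedding, sep = ",", row.names = FALSE,
                col.names = TRUE, quote = FALSE)
    if (!is.null(labels)) {
      m <- if (cfg$method == "spectral")
        clustering_metrics(labels, fitted$clusters$labels)
      else kmeans_evaluate(emb, labels, seed = seed)
      paths$metrics <- file.path(cfg$out_dir, "metrics.json")
      jsonlite::write_json(
        Filter(function(v) is.numeric(v) && length(v) == 1L,
               unclass(m)),
        paths$metrics, auto_unbox = TRUE, digits = NA)
    }
  }
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = cfg, seed = seed,
         package = as.character(utils::packageVersion("adaptdr")),
         r_version = R.version.string),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(fitted = fitted, paths = paths, config = cfg))
}
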