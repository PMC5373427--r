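#' Estimate cluster numbers for a matrix and build a run report
#'
#' The workhorse behind the command-line \code{estimate} command: reads a
#' numeric samples-by-features matrix, computes the average-linkage
#' hierarchy, applies the requested estimators (optionally wrapped in
#' mixing or leave-one-out consensus), and assembles a reproducible report.
#' The report embeds every parameter and the seed, so a run can be repeated
#' bit-identically; it serialises cleanly to JSON.
#'
#' Estimator failures (e.g. the elbow rule on a 3-point input, which has
#' too few merges) are recorded as warnings in the report rather than
#' aborting the remaining methods.
#'
#' @param input path to a delimited matrix file, or a numeric matrix.
#' @param methods character vector from \code{"elbow"}, \code{"maxdiff"},
#'   \code{"mode"}, \code{"gap"}, or \code{"all"}.
#' @param delimiter,header,labelCol parsing options for
#'   \code{\link{readMatrix}} (ignored when \code{input} is a matrix).
#' @param alpha,kMax,nReference estimator parameters.
#' @param resampling \code{"none"}, \code{"mixing"} or \code{"loocv"}.
#' @param M,L mixing parameters; \code{M = NULL} means \code{floor(N/2)}.
#' @param seed integer seed for stochastic components.
#' @param out optional path; when given the report is written there as JSON.
#' @param assignments optional path stem; when given, the cluster
#'   assignment at each method's estimate is written as a two-column CSV
#'   (\code{label, cluster_id}), one file per method.
#' @return the report, an S3 list of class \code{"dendrocutReport"} with
#'   elements \code{input}, \code{parameters}, \code{estimates} (per method:
#'   \code{k_hat} plus diagnostics), \code{warnings}, \code{seed},
#'   \code{version}.
#' @examples
#' x <- generateClusters(kTrue = 2, pointsPerCluster = 20, seed = 1)
#' rep <- cmdEstimate(x, methods = c("elbow", "maxdiff"))
#' vapply(rep$estimates, `[[`, 0, "k_hat")
#' @export
cmdEstimate <- function(input, methods = "all", delimiter = ",",
                        header = "auto", labelCol = NULL, alpha = 3,
                        kMax = 10, nReference = 50,
                        resampling = c("none", "mixing", "loocv"),
                        M = NULL, L = 100, seed = NULL, out = NULL,
                        assignments = NULL) {
  resampling <- match.arg(resampling)
  if ("all" %in% methods) methods <- c("elbow", "maxdiff", "mode", "gap")
  methods <- match.arg(methods, c("elbow", "maxdiff", "mode", "gap"),
                       several.ok = TRUE)
  if (is.character(input)) {
    x <- readMatrix(input, delimiter = delimiter, header = header,
                    labelCol = labelCol)
    inputDesc <- list(path = input, n = nrow(x), p = ncol(x))
  } else {
    x <- as.matrix(input)
    inputDesc <- list(path = NA_character_, n = nrow(x), p = ncol(x))
  }
  kMaxUse <- min(kMax, nrow(x) - 1L)
  warnings <- character(0)
  estimates <- list()
  ms <- tryCatch(computeLinkage(x), error = function(e) {
    warnings <<- c(warnings, conditionMessage(e)); NULL
  })
  methodSeeds <- deriveSeeds(seed, length(methods))
  for (i in seq_along(methods)) {
    m <- methods[i]
    est <- tryCatch({
      if (resampling == "mixing")
        mixedEstimate(x, m, M = M, L = L, seed = methodSeeds[i],
                      alpha = alpha, kMax = kMaxUse,
                      nReference = nReference)
      else if (resampling == "loocv")
        loocvEstimate(x, m, seed = methodSeeds[i], alpha = alpha,
                      kMax = kMaxUse, nReference = nReference)
      else if (m == "gap")
        estimateK(x, "gap", kMax = kMaxUse, nReference = nReference,
                  seed = methodSeeds[i])
      else if (!is.null(ms))
        .estimateFromMerges(ms, m, alpha = alpha)
      else
        stop("linkage computation failed")
    }, error = function(e) {
      warnings <<- c(warnings, sprintf("%s: %s", m, conditionMessage(e)))
      NULL
    })
    if (is.null(est)) next
    diag <- diagnostics(est)
    diag$histogram <- if (!is.null(diag$histogram))
      as.list(stats::setNames(as.integer(diag$histogram),
                              names(diag$histogram)))
    estimates[[m]] <- c(list(k_hat = kHat(est), method = methodName(est)),
                        diag[!vapply(diag, is.null, TRUE)])
    if (!is.null(assignments) && !is.null(ms)) {
      path <- if (length(methods) == 1L) assignments
              else sub("(\\.[^.]+)?$", sprintf("_%s\\1", m), assignments)
      writeAssignments(cutToK(ms, min(kHat(est), nrow(x))), path)
    }
  }
  report <- structure(
    list(input = inputDesc,
         parameters = list(methods = methods, alpha = alpha, kMax = kMaxUse,
                           nReference = nReference, resampling = resampling,
                           M = if (is.null(M)) NA_integer_ else as.integer(M),
                           L = L, linkage = "average",
                           metric = "euclidean"),
         estimates = estimates,
         warnings = warnings,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         version = as.character(utils::packageVersion("dendrocut"))),
    class = "dendrocutReport")
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  report
}

#' Run the simulation benchmark and write result tables
#'
#' Drives \code{\link{runExperiment}} over a set of true cluster numbers
#' and writes the stacked summary as long-format CSV and/or JSON. With the
#' defaults (\code{kTrue = 1:4}, 100 points per cluster, separation 6,
#' unit covariances, 200 runs) this reproduces the layout of the package's
#' reference benchmark.
#'
#' @param kTrue integer vector of true cluster numbers; default \code{1:4}.
#' @param methods estimators to evaluate.
#' @param nRuns simulated datasets per scenario; default 200.
#' @param covScales per-cluster covariance scales (recycled per scenario
#'   to its first \code{kTrue} entries); default unit.
#' @param resampling,M,L,alpha,kMax,nReference,pointsPerCluster,separation
#'   passed to \code{\link{runExperiment}}.
#' @param seed master seed; one sub-seed derived per scenario.
#' @param outCsv,outJson optional output paths.
#' @return the stacked summary data.frame, invisibly when written to file.
#' @export
cmdBenchmark <- function(kTrue = 1:4, methods = c("elbow", "maxdiff",
                                                  "mode", "gap"),
                         nRuns = 200, pointsPerCluster = 100,
                         separation = 6, covScales = NULL,
                         resampling = "none", M = NULL, L = 100, alpha = 3,
                         kMax = 10, nReference = 50, seed = NULL,
                         outCsv = NULL, outJson = NULL) {
  seeds <- deriveSeeds(seed, length(kTrue))
  res <- do.call(rbind, lapply(seq_along(kTrue), function(i) {
    k <- kTrue[i]
    runExperiment(k, methods = methods, nRuns = nRuns,
                  pointsPerCluster = pointsPerCluster,
                  separation = separation,
                  covScales = if (is.null(covScales)) NULL
                              else covScales[seq_len(k)],
                  resampling = resampling, M = M, L = L, alpha = alpha,
                  kMax = kMax, nReference = nReference, seed = seeds[i])
  }))
  rownames(res) <- NULL
  if (!is.null(outCsv))
    utils::write.csv(res, outCsv, row.names = FALSE, quote = FALSE)
  if (!is.null(outJson))
    jsonlite::write_json(res, outJson, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (is.null(outCsv) && is.null(outJson)) res else invisible(res)
}

#' Sample expression matrix for the case study
#'
#' Loads the 26-sample expression matrix distributed with the Bioconductor
#' \pkg{Biobase} package (its \code{sample.ExpressionSet}) and returns it
#' with samples in rows, the orientation the estimators expect
#' (\code{t(exprs(sample.ExpressionSet))}). On this matrix the elbow and
#' maximum-difference rules agree on 3 clusters, two of which are
#' singletons.
#'
#' @return numeric matrix, 26 samples by 500 features.
#' @export
expressionSetMatrix <- function() {
  if (!requireNamespace("Biobase", quietly = TRUE))
    stop("the Biobase package is required for the expression case study; ",
         "alternatively export the matrix to CSV and use readMatrix()")
  env <- new.env()
  utils::data("sample.ExpressionSet", package = "Biobase", envir = env)
  t(Biobase::exprs(env$sample.ExpressionSet))
}

#' @export
print.dendrocutReport <- function(x, ...) {
  cat(sprintf("dendrocut run report (version %s)\n", x$version))
  cat(sprintf("  input: %s (%d x %d)\n",
              ifelse(is.na(x$input$path), "<matrix>", x$input$path),
              x$input$n, x$input$p))
  for (m in names(x$estimates))
    cat(sprintf("  %-16s k_hat = %d\n", x$estimates[[m]]$method,
                x$estimates[[m]]$k_hat))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
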