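#' Ground truth attached to a synthetic dataset
#'
#' Every generator returns, alongside the dataset, a `ground_truth` object
#' recording the assay, the exact simulated truths (deflection fields, pulse
#' amplitudes, modulus, below-bilayer fraction, daily rate, ...) and the seed,
#' so downstream pipeline stages can be scored against what was simulated.
#'
#' @param assay one of `"pillar"`, `"tweezers"`, `"afm"`, `"invasion"`.
#' @param parameters named list of simulated truths.
#' @param seed integer seed the dataset was generated with.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(assay, parameters, seed) {
  assay <- match.arg(assay, c("pillar", "tweezers", "afm", "invasion"))
  structure(list(assay = assay, parameters = parameters, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> assay:", x$assay, " seed:", x$seed, "\n")
  cat("  truths:", paste(names(x$parameters), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a ground-truth JSON sidecar
#'
#' The sidecar shares the dataset's basename with extension `.truth.json`.
#'
#' @param truth a [ground_truth()] object.
#' @param path path of the dataset file the sidecar accompanies (its extension
#'   is replaced), or a path ending in `.json` used verbatim.
#' @return `write_ground_truth` returns the sidecar path invisibly;
#'   `read_ground_truth` returns the `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  side <- if (grepl("\\.json$", path)) path else
    paste0(sub("\\.[^.]+$", "", path), ".truth.json")
  jsonlite::write_json(unclass(truth), side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(x$assay, x$parameters, x$seed)
}
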