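#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Subprocess bridge to the bundled Python helper (inst/python/chemtools.py).
# All structure handling (RDKit) and nonlinear embeddings (umap-learn,
# scikit-learn) go through here; payloads travel as JSON temp files so a
# whole dataset is processed per interpreter start-up.

chemtools_script <- function() {
  path <- system.file("python", "chemtools.py", package = "chemgroup")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is on the source path
    path <- system.file("inst", "python", "chemtools.py", package = "chemgroup")
  }
  if (!nzchar(path)) stop("bundled chemtools.py not found")
  path
}

#' Locate the Python interpreter used for structure handling
#'
#' The interpreter is taken from the option `chemgroup.python`, the
#' environment variable `CHEMGROUP_PYTHON`, or `python` on the `PATH`,
#' in that order.
#'
#' @return Path to the Python executable.
#' @export
find_python <- function() {
  opt <- getOption("chemgroup.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("CHEMGROUP_PYTHON", "")
  if (nzchar(env)) return(env)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found on PATH; ",
                        "set options(chemgroup.python = ...)")
  unname(py)
}

run_chemtools <- function(command, payload) {
  in_path <- tempfile(fileext = ".json")
  out_path <- tempfile(fileext = ".json")
  on.exit(unlink(c(in_path, out_path)), add = TRUE)
  jsonlite::write_json(payload, in_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  err <- tempfile(fileext = ".log")
  on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(system2(
    find_python(), c(chemtools_script(), command, in_path, out_path),
    stdout = FALSE, stderr = err))
  if (!file.exists(out_path)) {
    msg <- if (file.exists(err)) paste(readLines(err, warn = FALSE),
                                       collapse = "\n") else ""
    stop("chemtools backend failed (", command, "): ", msg)
  }
  res <- jsonlite::read_json(out_path)
  if (!is.null(res$error)) stop("chemtools backend error (", command, "): ",
                                res$error)
  if (!identical(status, 0L)) stop("chemtools backend exited with status ",
                                   status)
  res
}
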