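# Bridge to the RDKit cheminformatics toolkit (Python), used for the
# toolkit-dependent metrics: default-sanitization validity, MMFF94
# single-point energies, SMARTS substructure matching, and canonical
# ring-system keys. Molecules are handed over as SDF, results come back as
# JSON. The valency-based stability metric deliberately does NOT go through
# this bridge, so stability and validity stay independent checks.

.rdkit_script <- function() {
  p <- system.file("python", "rdkit_tools.py", package = "dfmol")
  if (!nzchar(p)) p <- file.path("inst", "python", "rdkit_tools.py")
  p
}

#' Is the RDKit python bridge available?
#' @return Logical; `TRUE` if `python` with importable rdkit is on the PATH.
#' @export
rdkit_available <- function() {
  if (!is.null(.dfmol_env$rdkit_ok)) return(.dfmol_env$rdkit_ok)
  ok <- tryCatch({
    out <- suppressWarnings(system2("python", c("-c", shQuote("import rdkit")),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status")) || attr(out, "status") == 0
  }, error = function(e) FALSE)
  .dfmol_env$rdkit_ok <- ok
  ok
}

.dfmol_env <- new.env(parent = emptyenv())

#' Run RDKit tasks on a batch of molecules
#'
#' @param mols List of `dfmol_graph` (mask-free).
#' @param tasks Character vector from `sanitize`, `mmff`, `alerts`, `rings`.
#' @param smarts_path Path to a TSV alert catalog (required for `alerts`).
#' @return Named list of per-record results (NULL entries where a record
#'   failed sanitization).
#' @keywords internal
rdkit_batch <- function(mols, tasks, smarts_path = NULL) {
  if (!rdkit_available())
    stop("the RDKit python bridge is unavailable ('python' with rdkit ",
         "importable is required for this metric)")
  sdf <- tempfile(fileext = ".sdf")
  outj <- tempfile(fileext = ".json")
  on.exit(unlink(c(sdf, outj)), add = TRUE)
  write_sdf(mols, sdf)
  args <- c(.rdkit_script(), "--sdf", sdf, "--out", outj,
            "--tasks", paste(tasks, collapse = ","))
  if (!is.null(smarts_path)) args <- c(args, "--smarts", smarts_path)
  status <- system2("python", shQuote(args), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0)
    stop("rdkit helper failed: ", paste(status, collapse = "\n"))
  res <- jsonlite::fromJSON(outj, simplifyVector = FALSE)
  lapply(res, function(task_res) {
    if (length(task_res) != length(mols))
      stop("rdkit helper returned ", length(task_res), " records for ",
           length(mols), " molecules")
    task_res
  })
}
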