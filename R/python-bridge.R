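#' @keywords internal
.rmat_cache <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for molecule perception
#'
#' Molecule parsing, conformer generation, Bemis-Murcko scaffolds and
#' physicochemical descriptors are delegated to RDKit through a bundled
#' helper script. The interpreter is taken from the `RMAT_PYTHON`
#' environment variable when set, otherwise `python` on the `PATH`.
#'
#' @return Path to the Python executable.
#' @export
rmat_python <- function() {
  p <- Sys.getenv("RMAT_PYTHON", unset = "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) {
    stop("No Python interpreter found; set RMAT_PYTHON or put 'python' on the PATH.")
  }
  unname(p)
}

# One batched round-trip through the RDKit helper. Results are memoised for
# the lifetime of the R session (keyed on the full request) because tests and
# pipelines repeatedly featurize the same small fixture sets.
rdkit_query <- function(smiles = character(), seed = 1L, coords = FALSE,
                        descriptors = 0L, scaffold = FALSE, sdf_path = NULL) {
  cacheable <- is.null(sdf_path)
  key <- NULL
  if (cacheable) {
    stopifnot(is.character(smiles), length(smiles) >= 1L)
    key <- paste(seed, coords, descriptors, scaffold,
                 paste(smiles, collapse = "\r"), sep = "\r")
    hit <- .rmat_cache[["store"]][[key]]
    if (!is.null(hit)) return(hit)
  }

  script <- system.file("python", "rdkit_bridge.py", package = "rmat")
  if (!nzchar(script)) stop("rdkit_bridge.py not found in the installed package.")
  req <- list(smiles = as.list(smiles), seed = as.integer(seed),
              coords = isTRUE(coords), descriptors = as.integer(descriptors),
              scaffold = isTRUE(scaffold))
  if (!is.null(sdf_path)) req$sdf_path <- normalizePath(sdf_path)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  errfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA)
  status <- suppressWarnings(system2(rmat_python(), shQuote(script),
                                     stdin = infile, stdout = outfile,
                                     stderr = errfile))
  if (!identical(status, 0L)) {
    err <- tryCatch(paste(readLines(errfile, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("RDKit helper failed (status ", status, "):\n", err)
  }
  res <- jsonlite::read_json(outfile, simplifyVector = FALSE)

  if (cacheable) {
    if (is.null(.rmat_cache[["store"]])) .rmat_cache[["store"]] <- list()
    .rmat_cache[["store"]][[key]] <- res
  }
  res
}

#' Read molecules from an SDF V2000 file
#'
#' Stored 3D coordinates are used directly, skipping conformer generation.
#'
#' @param path SDF file.
#' @param scaffold Also record Bemis-Murcko scaffolds.
#' @return List of [rmat_molecule] objects.
#' @export
read_sdf <- function(path, scaffold = FALSE) {
  res <- rdkit_query(sdf_path = path, scaffold = scaffold)
  mols <- lapply(res$mols, molecule_from_record, smiles = basename(path))
  lapply(mols, function(m) {
    m$smiles <- m$canonical
    m
  })
}
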