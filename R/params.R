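#' Nearest-neighbor duplex energy parameters
#'
#' Loads the tab-separated parameter table that drives all duplex scoring:
#' stacking free energies for the six admissible pair types (Watson-Crick
#' plus G:U wobble), one-sided bulge penalties by loop length, two-sided
#' interior-loop penalties by total unpaired length, a duplex initiation
#' term and a terminal penalty charged at AU/GU duplex ends.  The bundled
#' default table (`nn_params_v1.tsv`) uses Turner-style Watson-Crick
#' stacking values; wobble-containing stacks are weakened relative to their
#' Watson-Crick analogs so that the perfect reverse-complement duplex is a
#' global energy lower bound for any admissible structure.
#'
#' @param path path to a parameter TSV; `NULL` loads the bundled table.
#' @return an object of class `energy_parameters`: a list with elements
#'   `stack` (6x6 numeric matrix, rows/cols named `AU, UA, GC, CG, GU, UG`),
#'   `bulge` (numeric, lengths `1..max_loop_side`), `interior` (numeric,
#'   total lengths `2..2*max_loop_side`), `init`, `terminal`,
#'   `max_loop_side`, and `version`.
#' @export
#' @examples
#' p <- energy_parameters()
#' p$stack["GC", "GC"]
energy_parameters <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.mirsite_env$default_params)) return(.mirsite_env$default_params)
    path <- system.file("extdata", "nn_params_v1.tsv", package = "mirsite")
    cache <- TRUE
  } else cache <- FALSE
  if (!file.exists(path)) stop("parameter table not found: ", path)
  hdr <- readLines(path, n = 10L)
  vline <- grep("^# version:", hdr, value = TRUE)
  version <- if (length(vline)) sub("^# version:\\s*", "", vline[1]) else "unversioned"
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = c("character", "character", "character", "numeric"))
  pair_names <- c("AU", "UA", "GC", "CG", "GU", "UG")
  st <- tab[tab$term == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pair_names, pair_names))
  stack[cbind(st$key1, st$key2)] <- st$value
  bu <- tab[tab$term == "bulge", ]
  bulge <- setNames(bu$value, bu$key1)[as.character(seq_len(nrow(bu)))]
  it <- tab[tab$term == "interior", ]
  interior <- setNames(it$value, it$key1)
  scal <- function(term) {
    v <- tab$value[tab$term == term]
    if (length(v) != 1L) stop("parameter table misses scalar term '", term, "'")
    v
  }
  obj <- structure(list(
    stack = stack, bulge = unname(bulge),
    interior = unname(interior[as.character(2:(2 * scal("max_loop_side")))]),
    init = scal("init"), terminal = scal("terminal"),
    max_loop_side = as.integer(scal("max_loop_side")),
    version = version), class = "energy_parameters")
  validate_energy_parameters(obj)
  if (cache) .mirsite_env$default_params <- obj
  obj
}

validate_energy_parameters <- function(p) {
  if (anyNA(p$stack)) stop("stacking table incomplete")
  if (any(p$stack > 0)) stop("stacking energies must be negative or zero")
  if (any(p$bulge < 0) || any(p$interior < 0)) stop("loop penalties must be non-negative")
  if (length(p$bulge) != p$max_loop_side) stop("bulge table must cover 1..max_loop_side")
  if (length(p$interior) != 2L * p$max_loop_side - 1L) {
    stop("interior table must cover 2..2*max_loop_side")
  }
  if (!is.character(p$version) || !nzchar(p$version)) stop("parameter table must carry a version")
  invisible(p)
}

#' @export
print.energy_parameters <- function(x, ...) {
  cat("Nearest-neighbor duplex parameters (", x$version, ")\n", sep = "")
  cat("  stacks: 6x6 table, range [", min(x$stack), ", ", max(x$stack), "] kcal/mol\n", sep = "")
  cat("  init ", x$init, ", terminal ", x$terminal,
      ", max loop side ", x$max_loop_side, "\n", sep = "")
  invisible(x)
}

# build an energy_parameters object from explicit pieces (used by tests)
#' Construct energy parameters from explicit components
#'
#' Mostly useful for testing alternative tables; see [energy_parameters()]
#' for the component semantics.
#'
#' @param stack 6x6 matrix with dimnames `AU, UA, GC, CG, GU, UG`.
#' @param bulge,interior penalty vectors (lengths `max_loop_side` and
#'   `2*max_loop_side - 1`).
#' @param init,terminal scalar energies (kcal/mol).
#' @param max_loop_side integer cap on the unpaired run per strand.
#' @param version version string carried by the table.
#' @return an `energy_parameters` object.
#' @export
make_energy_parameters <- function(stack, bulge, interior, init, terminal,
                                   max_loop_side = 15L, version = "custom") {
  obj <- structure(list(stack = stack, bulge = bulge, interior = interior,
                        init = init, terminal = terminal,
                        max_loop_side = as.integer(max_loop_side),
                        version = version), class = "energy_parameters")
  validate_energy_parameters(obj)
  obj
}
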