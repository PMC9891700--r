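# Lipid shorthand nomenclature: CLASS C:D sum composition, or
# CLASS(c1:d1/c2:d2) species-level chain composition.

#' Default lipid class vocabulary
#'
#' Class tokens accepted by [parse_lipid_name()]: glycerophospholipids (PC,
#' PE, PS, PG, PA, PI), their lyso forms, glycerolipids (TG, DG, MG),
#' sphingolipids (SM, Cer, HexCer), sterol and free fatty acyl classes.
#'
#' @return Character vector of class tokens.
#' @export
lipid_classes <- function() {
  c(
    "PC", "PE", "PS", "PG", "PA", "PI",
    "LPC", "LPE", "LPS", "LPG", "LPA", "LPI",
    "TG", "DG", "MG", "SM", "Cer", "HexCer", "CE", "FA"
  )
}

#' Parse a lipid shorthand name
#'
#' Accepts the sum-composition form `"PI 38:4"` (class, total carbons, total
#' double bonds) and the chain-level form `"PI(18:0/20:4)"`, whose chains sum
#' to the total composition. `"PI(38:4)"` is read as sum composition.
#'
#' @param raw Lipid name string.
#' @param classes Accepted class vocabulary (default [lipid_classes()]).
#' @return A list of class `lipid_name`: `raw`, `lipid_class`,
#'   `total_carbons`, `total_double_bonds`, `chains` (two-column matrix of
#'   per-chain carbons and double bonds, or `NULL` for sum composition).
#' @examples
#' parse_lipid_name("PI 38:4")
#' parse_lipid_name("PI(18:0/20:4)")
#' @export
parse_lipid_name <- function(raw, classes = lipid_classes()) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single lipid name string", call. = FALSE)
  }
  s <- trimws(raw)
  m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*)[ ]*\\(([0-9:/ ]+)\\)$", s))[[1L]]
  if (length(m) == 3L) {
    cls <- m[2L]
    body <- gsub(" ", "", m[3L])
  } else {
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*)[ ]+([0-9]+:[0-9]+)$", s))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("malformed lipid name '%s'", raw), call. = FALSE)
    }
    cls <- m[2L]
    body <- m[3L]
  }
  if (!cls %in% classes) {
    stop(sprintf("unknown lipid class token '%s' in '%s'", cls, raw), call. = FALSE)
  }
  parts <- strsplit(body, "/", fixed = TRUE)[[1L]]
  comp <- lapply(parts, function(p) {
    cd <- strsplit(p, ":", fixed = TRUE)[[1L]]
    if (length(cd) != 2L) {
      stop(sprintf("malformed composition '%s' in '%s'", p, raw), call. = FALSE)
    }
    v <- suppressWarnings(as.integer(cd))
    if (anyNA(v) || v[1L] <= 0L || v[2L] < 0L) {
      stop(sprintf("malformed composition '%s' in '%s'", p, raw), call. = FALSE)
    }
    v
  })
  if (length(comp) == 1L) {
    chains <- NULL
    total <- comp[[1L]]
  } else {
    chains <- do.call(rbind, comp)
    colnames(chains) <- c("carbons", "double_bonds")
    total <- colSums(chains)
  }
  structure(
    list(
      raw = raw, lipid_class = cls,
      total_carbons = unname(total[1L]), total_double_bonds = unname(total[2L]),
      chains = chains
    ),
    class = "lipid_name"
  )
}

#' @export
print.lipid_name <- function(x, ...) {
  cat(sprintf(
    "<lipid_name> %s: class %s, %d:%d%s\n", x$raw, x$lipid_class,
    x$total_carbons, x$total_double_bonds,
    if (is.null(x$chains)) "" else sprintf(" (%d chains)", nrow(x$chains))
  ))
  invisible(x)
}

#' Parse many lipid names into a data frame
#'
#' @param raw Character vector of lipid names.
#' @param classes Accepted class vocabulary.
#' @return `data.frame` with columns `raw`, `lipid_class`, `total_carbons`,
#'   `total_double_bonds`, `n_chains` (`NA` for sum composition).
#' @export
parse_lipid_names <- function(raw, classes = lipid_classes()) {
  parsed <- lapply(raw, parse_lipid_name, classes = classes)
  data.frame(
    raw = raw,
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    total_carbons = vapply(parsed, `[[`, numeric(1), "total_carbons"),
    total_double_bonds = vapply(parsed, `[[`, numeric(1), "total_double_bonds"),
    n_chains = vapply(parsed, function(p) {
      if (is.null(p$chains)) NA_integer_ else nrow(p$chains)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}
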