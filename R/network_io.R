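# YAML reading and writing of network definitions.
#
# The on-disk format mirrors the constructor fields: a mapping with
# top-level keys `inputs`, `genes`, `reactions` (and optionally
# `species_init`).  Keys are written in a fixed canonical order and
# numbers with 12 significant digits, so write -> read -> write
# round-trips byte-identically.

.input_keys <- c("species", "profile", "amplitude", "baseline", "period",
                 "phase", "duty")
.binding_keys <- c("tf", "lambda0", "mu", "role")
.gene_keys <- c("product", "logic", "bindings", "nu", "delta", "betas",
                "fixed_delay_steps", "init", "init_on")
.reaction_keys <- c("kind", "substrates", "enzyme", "product", "complex",
                    "lambda", "mu", "nu", "deltas", "init_complex",
                    "init_product")

.canon <- function(x, keys) {
  x <- unclass(x)
  out <- x[keys[keys %in% names(x)]]
  # drop NULLs and NAs that only pad optional fields
  out[!vapply(out, function(v) is.null(v) || (length(v) == 1L && is.na(v)),
              logical(1))]
}

#' Write a network definition to a YAML file
#'
#' @param spec a \code{\link{network_spec}}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_network <- function(spec, path) {
  doc <- list(
    inputs = lapply(spec$inputs, .canon, keys = .input_keys),
    genes = lapply(spec$genes, function(g) {
      g2 <- .canon(g, .gene_keys)
      g2$bindings <- lapply(g$bindings, .canon, keys = .binding_keys)
      if (length(g$betas) == 0) g2$betas <- NULL
      g2
    }),
    reactions = lapply(spec$reactions, .canon, keys = .reaction_keys))
  if (length(spec$species_init))
    doc$species_init <- as.list(spec$species_init)
  txt <- yaml::as.yaml(doc, precision = 12L)
  writeLines(txt, path)
  invisible(path)
}

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where, paste(bad, collapse = ", ")))
}

#' Read a network definition from a YAML file
#'
#' Unknown keys are rejected with an error.
#'
#' @param path YAML file written by \code{\link{write_network}} (or by hand
#'   in the same layout)
#' @return a \code{\link{network_spec}}
#' @export
read_network <- function(path) {
  doc <- yaml::yaml.load_file(path)
  .check_keys(doc, c("inputs", "genes", "reactions", "species_init"), "document")
  inputs <- lapply(doc$inputs, function(i) {
    .check_keys(i, .input_keys, "input")
    do.call(input_spec, i)
  })
  genes <- lapply(doc$genes, function(g) {
    .check_keys(g, .gene_keys, "gene")
    g$bindings <- lapply(g$bindings, function(b) {
      .check_keys(b, .binding_keys, "binding")
      do.call(tf_binding, b)
    })
    do.call(gene_spec, g)
  })
  reactions <- lapply(doc$reactions, function(r) {
    .check_keys(r, .reaction_keys, "reaction")
    r$substrates <- unlist(r$substrates)
    if (!is.null(r$deltas)) r$deltas <- unlist(r$deltas)
    do.call(reaction_spec, r)
  })
  network_spec(inputs = inputs, genes = genes, reactions = reactions,
               species_init = unlist(doc$species_init) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
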