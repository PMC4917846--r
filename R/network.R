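#' Reaction-network dialect options
#'
#' Controls how reaction files are interpreted: which metabolite tokens are
#' boundary (external) species, which species are dropped from the
#' stoichiometric matrix entirely (protons by default, since intracellular pH
#' is rarely measured), and whether unknown metabolites are auto-created.
#'
#' @param external_suffix suffix marking boundary metabolites (default "_e").
#' @param external_ids explicit metabolite ids treated as external, in
#'   addition to the suffix rule.
#' @param ignored_species species excluded from the stoichiometric matrix
#'   altogether; matching is case-insensitive. Default `"H+"`.
#' @param strict if `TRUE`, metabolites must be pre-declared (via
#'   `known_metabolites`) and unknown ones are an error; default auto-creates.
#' @param known_metabolites optional character vector of allowed ids.
#' @return a list of class `kcone_dialect`.
#' @export
network_dialect <- function(external_suffix = "_e", external_ids = character(),
                            ignored_species = "H+", strict = FALSE,
                            known_metabolites = NULL) {
  structure(list(external_suffix = external_suffix,
                 external_ids = external_ids,
                 ignored_species = tolower(ignored_species),
                 strict = strict,
                 known_metabolites = known_metabolites),
            class = "kcone_dialect")
}

# parse one side of a reaction string into a named coefficient vector.
# terms are separated by " + " (plus with surrounding whitespace) so that
# ionic species names such as "H+" survive.
parse_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(numeric())
  terms <- strsplit(side, "\\s+\\+\\s+")[[1]]
  coefs <- numeric(0)
  for (term in terms) {
    term <- trimws(term)
    if (term == "") next
    toks <- strsplit(term, "\\s+")[[1]]
    cf <- suppressWarnings(as.numeric(toks[1]))
    if (length(toks) > 1 && !is.na(cf)) {
      met <- paste(toks[-1], collapse = " ")
    } else {
      cf <- 1
      met <- paste(toks, collapse = " ")
    }
    if (cf <= 0) stop("non-positive stoichiometry in term: ", term)
    coefs[met] <- if (met %in% names(coefs)) coefs[[met]] + cf else cf
  }
  coefs
}

parse_reaction_string <- function(str) {
  rev <- grepl("<=>", str, fixed = TRUE)
  arrow <- if (rev) "<=>" else "->"
  if (!rev && !grepl("->", str, fixed = TRUE))
    stop("no reaction arrow ('->' or '<=>') in: ", str)
  sides <- strsplit(str, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("multiple arrows in: ", str)
  if (length(sides) == 1) sides <- c(sides, "")
  lhs <- parse_side(sides[1])
  rhs <- parse_side(sides[2])
  both <- intersect(names(lhs), names(rhs))
  if (length(both) > 0)
    stop("metabolite(s) on both sides of reaction: ",
         paste(both, collapse = ", "))
  list(substrates = lhs, products = rhs, reversible = rev)
}

#' Build a reaction network from parsed reactions
#'
#' Internal constructor shared by [parse_network()] and the synthetic-network
#' generators. Builds the full stoichiometry matrix (all species) and the
#' stoichiometric matrix `S` restricted to internal, non-ignored metabolites.
#'
#' @param reactions data.frame with columns `id`, `reaction`, `reversible`,
#'   `pathway`, `kegg`.
#' @param parsed list of parsed reaction structures (substrates/products).
#' @param dialect a [network_dialect()].
#' @return object of class `reaction_network`.
#' @keywords internal
build_network <- function(reactions, parsed, dialect = network_dialect()) {
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  mets <- character(0)
  for (p in parsed) mets <- c(mets, names(p$substrates), names(p$products))
  mets <- unique(mets)  # file order
  if (dialect$strict && !is.null(dialect$known_metabolites)) {
    unknown <- setdiff(mets, dialect$known_metabolites)
    if (length(unknown) > 0)
      stop("unknown metabolite(s) in strict mode: ",
           paste(unknown, collapse = ", "))
  }
  external <- endsWith(mets, dialect$external_suffix) |
    mets %in% dialect$external_ids
  ignored <- tolower(mets) %in% dialect$ignored_species

  stoich <- matrix(0, nrow = length(mets), ncol = nrow(reactions),
                   dimnames = list(mets, reactions$id))
  for (j in seq_along(parsed)) {
    p <- parsed[[j]]
    stoich[names(p$substrates), j] <- stoich[names(p$substrates), j] -
      p$substrates
    stoich[names(p$products), j] <- stoich[names(p$products), j] + p$products
  }
  internal <- !external & !ignored
  structure(list(
    metabolites = data.frame(id = mets, external = external,
                             ignored = ignored, stringsAsFactors = FALSE),
    reactions = reactions,
    stoich = stoich,
    S = stoich[internal, , drop = FALSE],
    dialect = dialect
  ), class = "reaction_network")
}

#' Parse a reaction-network file
#'
#' Reads a CSV/TSV model file with columns `id`, `reaction`, `reversible`
#' (optional; the `<=>` arrow also marks reversibility), `pathway` and `kegg`
#' (both optional). Reaction strings follow the grammar
#' `"2 A + B -> C"` / `"A <=> B"`; an empty side denotes an exchange with the
#' environment (e.g. `"-> A"` is an import). Metabolites ending in the
#' dialect's external suffix are boundary species and excluded from the
#' stoichiometric matrix, as are ignored species (protons by default).
#'
#' @param path file path.
#' @param dialect a [network_dialect()].
#' @param sep field separator; guessed from the file extension by default.
#' @return a `reaction_network`: list with `metabolites`, `reactions`, the
#'   full `stoich` matrix and the internal-metabolite matrix `S` (rows =
#'   internal metabolites, columns = reactions; negative entries are
#'   substrates).
#' @export
parse_network <- function(path, dialect = network_dialect(), sep = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           comment.char = "#", quote = "\"")
  if (!all(c("id", "reaction") %in% names(tab)))
    stop("network file must have 'id' and 'reaction' columns")
  parsed <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parsed[[i]] <- tryCatch(parse_reaction_string(tab$reaction[i]),
      error = function(e) stop("parse error at line ", i + 1, " (", tab$id[i],
                               "): ", conditionMessage(e), call. = FALSE))
  }
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  if ("reversible" %in% names(tab))
    reversible <- reversible | as.logical(tab$reversible)
  for (i in seq_along(parsed)) parsed[[i]]$reversible <- reversible[i]
  reactions <- data.frame(
    id = tab$id,
    reversible = reversible,
    pathway = if ("pathway" %in% names(tab)) tab$pathway else NA_character_,
    kegg = if ("kegg" %in% names(tab)) tab$kegg else NA_character_,
    stringsAsFactors = FALSE)
  net <- build_network(reactions, parsed, dialect)
  net$parsed <- parsed
  net
}

#' Construct a network from reaction strings in code
#'
#' @param strings named character vector `id = "A -> B"`.
#' @param pathway optional pathway annotation per reaction.
#' @param dialect a [network_dialect()].
#' @return a `reaction_network`.
#' @export
network_from_strings <- function(strings, pathway = NA_character_,
                                 dialect = network_dialect()) {
  parsed <- lapply(strings, parse_reaction_string)
  reactions <- data.frame(
    id = names(strings),
    reversible = vapply(parsed, `[[`, logical(1), "reversible"),
    pathway = rep_len(pathway, length(strings)),
    kegg = NA_character_, stringsAsFactors = FALSE)
  net <- build_network(reactions, parsed, dialect)
  net$parsed <- unname(parsed)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", nrow(x$reactions), "reactions (",
      sum(x$reactions$reversible), "reversible ),",
      nrow(x$S), "internal /", nrow(x$metabolites), "total metabolites\n")
  invisible(x)
}

# substrate exponent matrix: |s_ji| for substrates only (species x reaction),
# over all species (internal and external).
substrate_exponents <- function(net) {
  ex <- -net$stoich
  ex[ex < 0] <- 0
  ex
}

#' Split reversible reactions into forward/backward pairs
#'
#' Each reversible reaction `r` becomes irreversible `r_f` and `r_b`, the
#' backward column being the negated forward column, so that the resulting
#' network admits a strictly non-negative flux and k-cone. Irreversible
#' reactions pass through unchanged.
#'
#' @param net a `reaction_network`.
#' @return a `reaction_network` with `reversible` all `FALSE`; attribute
#'   `split_map` maps original ids to new ids.
#' @export
split_reversible <- function(net) {
  parsed <- net$parsed
  if (is.null(parsed)) stop("network lacks parsed reaction structures")
  new_parsed <- list()
  new_ids <- character(0)
  new_pathway <- character(0)
  new_kegg <- character(0)
  split_map <- list()
  for (i in seq_len(nrow(net$reactions))) {
    p <- parsed[[i]]
    id <- net$reactions$id[i]
    if (net$reactions$reversible[i]) {
      fwd <- list(substrates = p$substrates, products = p$products,
                  reversible = FALSE)
      bwd <- list(substrates = p$products, products = p$substrates,
                  reversible = FALSE)
      new_parsed <- c(new_parsed, list(fwd, bwd))
      new_ids <- c(new_ids, paste0(id, "_f"), paste0(id, "_b"))
      new_pathway <- c(new_pathway, rep(net$reactions$pathway[i], 2))
      new_kegg <- c(new_kegg, rep(net$reactions$kegg[i], 2))
      split_map[[id]] <- c(paste0(id, "_f"), paste0(id, "_b"))
    } else {
      new_parsed <- c(new_parsed, list(modifyList(p, list(reversible = FALSE))))
      new_ids <- c(new_ids, id)
      new_pathway <- c(new_pathway, net$reactions$pathway[i])
      new_kegg <- c(new_kegg, net$reactions$kegg[i])
      split_map[[id]] <- id
    }
  }
  reactions <- data.frame(id = new_ids, reversible = FALSE,
                          pathway = new_pathway, kegg = new_kegg,
                          stringsAsFactors = FALSE)
  out <- build_network(reactions, new_parsed, net$dialect)
  out$parsed <- new_parsed
  attr(out, "split_map") <- split_map
  # default kinetic constants of the toy fixtures are named for the split
  # network, so they carry over unchanged
  attr(out, "k_default") <- attr(net, "k_default")
  out
}

#' Validate a reaction network (report only)
#'
#' Flags dead-end internal metabolites (produced but never consumed or vice
#' versa), duplicated stoichiometric columns, and all-zero columns. Never
#' mutates its input.
#'
#' @param net a `reaction_network`.
#' @return list with `dead_ends`, `duplicate_columns`, `zero_columns`, `ok`.
#' @export
validate_network <- function(net) {
  S <- net$S
  produced <- rowSums(S > 0) > 0
  consumed <- rowSums(S < 0) > 0
  dead <- rownames(S)[xor(produced, consumed) | (!produced & !consumed)]
  key <- apply(round(S, 10), 2, paste, collapse = ",")
  dup <- net$reactions$id[duplicated(key) | duplicated(key, fromLast = TRUE)]
  zero <- net$reactions$id[colSums(abs(net$stoich)) == 0]
  list(dead_ends = dead, duplicate_columns = dup, zero_columns = zero,
       ok = length(dead) == 0 && length(dup) == 0 && length(zero) == 0)
}

#' Write a network back to CSV
#'
#' Emits the same dialect read by [parse_network()]; a round trip reproduces
#' the stoichiometric matrix.
#'
#' @param net a `reaction_network`.
#' @param path output file.
#' @export
write_network <- function(net, path) {
  fmt_side <- function(v) {
    if (length(v) == 0) return("")
    paste(ifelse(v == 1, names(v), paste(format(v, trim = TRUE), names(v))),
          collapse = " + ")
  }
  strs <- vapply(seq_len(nrow(net$reactions)), function(i) {
    p <- net$parsed[[i]]
    arrow <- if (net$reactions$reversible[i]) "<=>" else "->"
    trimws(paste(fmt_side(p$substrates), arrow, fmt_side(p$products)))
  }, character(1))
  utils::write.csv(data.frame(id = net$reactions$id, reaction = strs,
                              reversible = net$reactions$reversible,
                              pathway = net$reactions$pathway,
                              kegg = net$reactions$kegg,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
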