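SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
META_NS <- "https://rearmech.r-pkg/annotations"

#' Export a compiled model as SBML Level 3
#'
#' One SBML species per pool (active, inactive and binding-complex pools) in
#' a single unit-size compartment, one reaction per elementary mass-action
#' reaction with an explicit kinetic law (global parameter times reactant
#' species), and all rate constants as global parameters. The clamped
#' input's pools are flagged as boundary conditions. Category and rate-class
#' metadata travel in a package annotation namespace so a re-import can
#' reconstruct the model exactly.
#'
#' @param model an `rm_model`.
#' @param path optional file path; when given the document is written there.
#' @param ics optional `rm_state` supplying initial amounts (defaults to the
#'   diagram's default initial conditions).
#' @return an `xml2::xml_document`, invisibly when `path` is given.
#' @export
to_sbml <- function(model, path = NULL,
                    ics = if (!is.null(model$wiring))
                      default_initial_conditions(model$wiring)
                    else model$initial) {
  diagram <- model$wiring
  input_pools <- if (!is.null(diagram))
    paste0(diagram$input_species, c("_a", "_i"))
  else model$pools[rowSums(abs(model$stoich)) == 0]
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    '  <model id="cell_rear_retraction" name="Mechanochemical cell rear retraction model">',
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (pool in model$pools) {
    extra <- ""
    sp_name <- sub("_(a|i)$", "", pool)
    if (!is.null(diagram) && sp_name %in% diagram$species$name) {
      cat_ <- diagram$species$category[diagram$species$name == sp_name]
      extra <- sprintf(' rearmech:category="%s" rearmech:species="%s" rearmech:pool="%s"',
                       cat_, sp_name,
                       if (endsWith(pool, "_a")) "active" else "inactive")
    } else {
      extra <- ' rearmech:pool="complex"'
    }
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="cell" initialAmount="%.17g" hasOnlySubstanceUnits="true" boundaryCondition="%s" constant="false" xmlns:rearmech="%s"%s/>',
      pool, unname(ics[[pool]]),
      if (pool %in% input_pools) "true" else "false", META_NS, extra))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_len(nrow(model$parameters))) {
    p <- model$parameters[k, ]
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%.17g" constant="false" xmlns:rearmech="%s" rearmech:class="%s" rearmech:isReverse="%s"%s/>',
      p$name, p$value, META_NS, p$class, tolower(as.character(p$is_reverse)),
      if (!is.na(p$paired_forward))
        sprintf(' rearmech:pairedForward="%s"', p$paired_forward) else ""))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    lines <- c(lines, sprintf(
      '      <reaction id="r%03d" reversible="false" xmlns:rearmech="%s" rearmech:kind="%s">',
      j, META_NS, r$kind))
    lines <- c(lines, '        <listOfReactants>')
    for (nm in names(r$reactants))
      lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
        nm, r$reactants[[nm]]))
    lines <- c(lines, '        </listOfReactants>', '        <listOfProducts>')
    for (nm in names(r$products))
      lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
        nm, r$products[[nm]]))
    math_terms <- c(r$rate_constant,
                    rep(names(r$reactants), times = r$reactants))
    lines <- c(lines,
               '        </listOfProducts>',
               '        <kineticLaw>',
               sprintf('          <math xmlns="%s">', MATHML_NS),
               '            <apply>',
               '              <times/>',
               sprintf('              <ci> %s </ci>', esc(math_terms)),
               '            </apply>',
               '          </math>',
               '        </kineticLaw>',
               '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Structural validation of an SBML document
#'
#' Checks the subset of SBML Level 3 structure this package relies on:
#' well-formed XML in the SBML namespace with level/version attributes, a
#' model with compartment, species (each with id, compartment and
#' initialAmount), global parameters with numeric values, and reactions
#' whose kinetic laws are MathML products of one known parameter and the
#' reaction's reactant species (mass action).
#'
#' @param doc an `xml2::xml_document` or path.
#' @return an `rm_validation` object.
#' @export
validate_sbml_document <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  v <- list()
  add <- function(rule, message) v[[length(v) + 1L]] <<- data.frame(
    rule = rule, message = message, stringsAsFactors = FALSE)
  root <- xml2::xml_name(doc)
  if (root != "sbml") add("root", paste("root element is", root))
  ns <- xml2::xml_ns(doc)
  if (!SBML_NS %in% ns) add("namespace", "SBML level 3 core namespace missing")
  if (!identical(xml2::xml_attr(doc, "level"), "3"))
    add("level", "level attribute must be 3")
  model <- xml2::xml_find_first(doc, ".//d1:model", ns)
  if (inherits(model, "xml_missing")) {
    add("model", "no model element")
  } else {
    sp <- xml2::xml_find_all(doc, ".//d1:species", ns)
    if (!length(sp)) add("species", "no species defined")
    bad <- vapply(sp, function(s)
      is.na(xml2::xml_attr(s, "id")) || is.na(xml2::xml_attr(s, "compartment")) ||
        is.na(suppressWarnings(as.numeric(xml2::xml_attr(s, "initialAmount")))),
      logical(1))
    if (any(bad)) add("species", sprintf("%d species missing id/compartment/initialAmount", sum(bad)))
    par_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:parameter", ns), "id")
    for (rx in xml2::xml_find_all(doc, ".//d1:reaction", ns)) {
      rid <- xml2::xml_attr(rx, "id")
      kl <- xml2::xml_find_first(rx, ".//d1:kineticLaw", ns)
      if (inherits(kl, "xml_missing")) { add("kinetic_law", paste(rid, "has no kineticLaw")); next }
      parsed <- tryCatch(parse_mass_action(rx, ns, par_ids), error = function(e) e)
      if (inherits(parsed, "error"))
        add("kinetic_law", paste0(rid, ": ", conditionMessage(parsed)))
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), message = character(), stringsAsFactors = FALSE)
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "rm_validation")
}

# Parse a reaction's kinetic law as k * prod(reactants); errors on anything
# that is not plain mass action.
parse_mass_action <- function(rx, ns, par_ids) {
  kl <- xml2::xml_find_first(rx, ".//d1:kineticLaw", ns)
  apply_node <- xml2::xml_find_first(kl, ".//m:apply",
                                     c(m = MATHML_NS, ns))
  if (inherits(apply_node, "xml_missing"))
    stop("kinetic law carries no MathML apply node")
  kids <- xml2::xml_children(apply_node)
  if (xml2::xml_name(kids[[1]]) != "times")
    stop("kinetic law is not a product (found <",
         xml2::xml_name(kids[[1]]), "/>): only mass action is supported")
  cis <- trimws(xml2::xml_text(kids[-1]))
  if (any(xml2::xml_name(kids[-1]) != "ci"))
    stop("kinetic law factors must all be <ci> references")
  is_par <- cis %in% par_ids
  if (sum(is_par) != 1L)
    stop("kinetic law must reference exactly one rate parameter")
  reac <- xml2::xml_find_all(rx, ".//d1:listOfReactants/d1:speciesReference", ns)
  rsp <- xml2::xml_attr(reac, "species")
  rst <- as.numeric(xml2::xml_attr(reac, "stoichiometry"))
  rst[is.na(rst)] <- 1
  expected <- sort(rep(rsp, times = rst))
  if (!identical(sort(cis[!is_par]), expected))
    stop("kinetic law factors do not match the reactant list (not mass action)")
  list(rate_constant = cis[is_par], reactants = stats::setNames(rst, rsp))
}

#' Import an SBML mass-action model
#'
#' Rebuilds a compiled model from an SBML Level 3 document produced by
#' [to_sbml()] (or any document restricted to mass-action kinetic laws of
#' the form parameter times reactants). Documents with other rate-law forms
#' are rejected, naming the offending reaction.
#'
#' @param doc an `xml2::xml_document` or file path.
#' @return an object of class `rm_model` (without a wiring diagram; the
#'   `wiring` field holds only the input species inferred from boundary
#'   flags, if any).
#' @export
from_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  ns <- xml2::xml_ns(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//d1:species", ns)
  pools <- xml2::xml_attr(sp_nodes, "id")
  init <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  par_nodes <- xml2::xml_find_all(doc, ".//d1:parameter", ns)
  parameters <- data.frame(
    name = xml2::xml_attr(par_nodes, "id"),
    value = as.numeric(xml2::xml_attr(par_nodes, "value")),
    class = ifelse(is.na(xml2::xml_attr(par_nodes, "class")), "unknown",
                   xml2::xml_attr(par_nodes, "class")),
    is_reverse = xml2::xml_attr(par_nodes, "isReverse") %in% "true",
    paired_forward = xml2::xml_attr(par_nodes, "pairedForward"),
    stringsAsFactors = FALSE)

  reactions <- list()
  for (rx in xml2::xml_find_all(doc, ".//d1:reaction", ns)) {
    rid <- xml2::xml_attr(rx, "id")
    parsed <- tryCatch(parse_mass_action(rx, ns, parameters$name),
                       error = function(e)
                         stop("reaction ", rid, ": ", conditionMessage(e),
                              call. = FALSE))
    prod_nodes <- xml2::xml_find_all(
      rx, ".//d1:listOfProducts/d1:speciesReference", ns)
    pst <- as.numeric(xml2::xml_attr(prod_nodes, "stoichiometry"))
    pst[is.na(pst)] <- 1
    kind <- xml2::xml_attr(rx, "kind")
    reactions[[length(reactions) + 1L]] <- elementary_reaction(
      if (kind %in% c("binding", "conversion", "one_step_state_change",
                      "turnover")) kind else "conversion",
      parsed$reactants,
      stats::setNames(pst, xml2::xml_attr(prod_nodes, "species")),
      parsed$rate_constant)
  }

  pidx <- stats::setNames(seq_along(pools), pools)
  n_r <- length(reactions)
  N <- matrix(0, nrow = length(pools), ncol = n_r,
              dimnames = list(pools, NULL))
  i1 <- integer(n_r); i2 <- integer(n_r)
  for (j in seq_len(n_r)) {
    r <- reactions[[j]]
    for (nm in names(r$reactants)) N[nm, j] <- N[nm, j] - r$reactants[[nm]]
    for (nm in names(r$products)) N[nm, j] <- N[nm, j] + r$products[[nm]]
    ridx <- rep(pidx[names(r$reactants)], times = r$reactants)
    i1[j] <- ridx[1L]
    i2[j] <- if (length(ridx) == 2L) ridx[2L] else 0L
  }
  N[boundary, ] <- 0
  structure(list(
    wiring = NULL,
    reactions = reactions,
    parameters = parameters,
    pools = pools,
    initial = stats::setNames(init, pools),
    stoich = N,
    reactant1 = i1,
    reactant2 = i2,
    k_index = match(vapply(reactions, `[[`, character(1), "rate_constant"),
                    parameters$name),
    observables = NULL),
    class = "rm_model")
}

#' Diff two models' inventories
#'
#' Reports species/pool and reaction count differences plus pools present in
#' only one model; used to compare a locally supplied deposited model
#' against the canonical reconstruction.
#'
#' @param a,b `rm_model`s.
#' @return a list with `pool_counts`, `reaction_counts`, `only_in_a`,
#'   `only_in_b`.
#' @export
model_diff <- function(a, b) {
  list(pool_counts = c(a = length(a$pools), b = length(b$pools)),
       reaction_counts = c(a = length(a$reactions), b = length(b$reactions)),
       only_in_a = setdiff(a$pools, b$pools),
       only_in_b = setdiff(b$pools, a$pools))
}
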