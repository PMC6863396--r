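#' Species definition
#'
#' One row of a wiring diagram's species roster. Every variable in the model
#' -- protein, complex or biophysical entity -- carries a conserved moiety
#' split between an active pool, an inactive pool and (for proteins engaged
#' in two-step reactions) transient binding complexes. Activity is expressed
#' on a normalised 0--100 scale so protein and biophysical levels are
#' directly comparable.
#'
#' @param name identifier; must not contain underscores (pool names are
#'   derived by suffixing `_a` / `_i`).
#' @param category one of `"protein"`, `"complex"`, `"biophysical"`.
#' @param total_moiety conserved total, activity units (default 100).
#' @param initial_active default initial active amount in `[0, total_moiety]`.
#' @param has_turnover whether a first-order active-to-inactive turnover flux
#'   applies to the species.
#' @param is_clamped_input whether the species is the clamped external input
#'   (held constant between events, no turnover, never consumed).
#' @param display_label free-text label for tables and plots.
#' @return a one-row `data.frame`.
#' @export
species_def <- function(name, category,
                        total_moiety = 100, initial_active = 0,
                        has_turnover = TRUE, is_clamped_input = FALSE,
                        display_label = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("_", name, fixed = TRUE))
    stop("species name must not contain '_': ", name)
  category <- match.arg(category, c("protein", "complex", "biophysical"))
  data.frame(name = name, category = category,
             total_moiety = as.numeric(total_moiety),
             initial_active = as.numeric(initial_active),
             has_turnover = isTRUE(has_turnover),
             is_clamped_input = isTRUE(is_clamped_input),
             display_label = display_label,
             stringsAsFactors = FALSE)
}

#' Interaction edge definition
#'
#' A signed, mechanism-annotated interaction. Protein-protein interactions
#' are two-step (binding then conversion); interactions involving a
#' biophysical entity are single-step state changes. Reversibility follows
#' the formulation rules: all-protein and all-biophysical reactions are
#' reversible (backward rate at most 10% of forward) except the designated
#' irreversible edges, and mixed protein/biophysical edges are irreversible.
#'
#' @param source,target species names.
#' @param effect `"activate"` or `"inhibit"`.
#' @param mechanism `"two_step"` or `"one_step"`.
#' @param reversible logical.
#' @param rate_class `"protein"` or `"biophysical"`; defaults by mechanism.
#' @param provenance free-text citation note.
#' @return a one-row `data.frame`.
#' @export
edge_def <- function(source, target, effect, mechanism,
                     reversible = FALSE,
                     rate_class = if (mechanism == "two_step") "protein" else "biophysical",
                     provenance = "") {
  effect <- match.arg(effect, c("activate", "inhibit"))
  mechanism <- match.arg(mechanism, c("two_step", "one_step"))
  rate_class <- match.arg(rate_class, c("protein", "biophysical"))
  data.frame(source = source, target = target, effect = effect,
             mechanism = mechanism, reversible = isTRUE(reversible),
             rate_class = rate_class, provenance = provenance,
             stringsAsFactors = FALSE)
}

#' Wiring diagram
#'
#' Bundles a species roster and an edge list into an `rm_wiring` object, the
#' declarative topology from which the mass-action reaction system is
#' compiled.
#'
#' @param species `data.frame` of stacked [species_def()] rows.
#' @param edges `data.frame` of stacked [edge_def()] rows.
#' @return an object of class `rm_wiring` with elements `species`, `edges`
#'   and `input_species`.
#' @export
wiring_diagram <- function(species, edges) {
  input <- species$name[species$is_clamped_input]
  structure(list(species = species, edges = edges,
                 input_species = if (length(input)) input[1L] else NA_character_),
            class = "rm_wiring")
}

#' @export
print.rm_wiring <- function(x, ...) {
  cat("rm_wiring:", nrow(x$species), "species,", nrow(x$edges), "edges\n")
  cat("  categories:",
      paste(sprintf("%s=%d", names(table(x$species$category)),
                    as.integer(table(x$species$category))), collapse = ", "), "\n")
  cat("  clamped input:", x$input_species, "\n")
  invisible(x)
}

# Edges designated irreversible by the formulation rules regardless of
# endpoint categories: decreased tension -> caveolae, and the two inputs of
# acto-myosin contractility.
.irreversible_edges <- matrix(c(
  "MembraneTension", "Caveolae",
  "ActinAlignment",  "ActoMyosinContractility",
  "pMLC",            "ActoMyosinContractility"), ncol = 2, byrow = TRUE)

#' Canonical rear-retraction wiring diagram
#'
#' The shipped 19-variable network of the caveolae-RhoA-actomyosin axis:
#' 12 proteins (Src, p190RhoGAP, Ect2, RhoA, ROCK1, PKN2, DRF, LIMK, Cofilin,
#' CPI17, MLCP, Actin), the caveolae complex as a single node, and 6
#' biophysical entities (polarized substrate stiffness as the clamped input,
#' membrane tension with active = decreased tension, actin alignment,
#' phosphorylated myosin light chain, acto-myosin contractility, and rear
#' retraction itself). Actin's active pool is F-actin and its inactive pool
#' G-actin. pMLC has no turnover term (its phosphatase MLCP is explicit) and
#' is activated in one step.
#'
#' @return an `rm_wiring` object.
#' @export
canonical_wiring <- function() {
  sp <- rbind(
    species_def("Src", "protein", initial_active = 50,
                display_label = "Src kinase"),
    species_def("p190RhoGAP", "protein", display_label = "p190RhoGAP"),
    species_def("Ect2", "protein", display_label = "Ect2 (RhoA GEF)"),
    species_def("RhoA", "protein", display_label = "RhoA GTPase"),
    species_def("ROCK1", "protein", display_label = "ROCK1 kinase"),
    species_def("PKN2", "protein", display_label = "PKN2 kinase"),
    species_def("DRF", "protein", display_label = "Diaphanous-related formin"),
    species_def("LIMK", "protein", display_label = "LIM kinase"),
    species_def("Cofilin", "protein", initial_active = 100,
                display_label = "Cofilin"),
    species_def("CPI17", "protein", display_label = "CPI-17"),
    species_def("MLCP", "protein", initial_active = 100,
                display_label = "Myosin light chain phosphatase"),
    species_def("Actin", "protein",
                display_label = "Actin (active = F-actin)"),
    species_def("Caveolae", "complex", display_label = "Caveolae (Cav-1)"),
    species_def("PolarizedSubstrateStiffness", "biophysical",
                initial_active = 100, has_turnover = FALSE,
                is_clamped_input = TRUE,
                display_label = "Polarized substrate stiffness (input)"),
    species_def("MembraneTension", "biophysical",
                display_label = "Decreased rear membrane tension"),
    species_def("ActinAlignment", "biophysical",
                display_label = "Rear F-actin alignment"),
    species_def("pMLC", "biophysical", has_turnover = FALSE,
                display_label = "Phosphorylated myosin light chain"),
    species_def("ActoMyosinContractility", "biophysical",
                display_label = "Acto-myosin contractility"),
    species_def("RearRetraction", "biophysical",
                display_label = "Rear retraction / recoil"))

  e <- function(source, target, effect, mechanism, provenance = "") {
    categories <- sp$category[match(c(source, target), sp$name)]
    mixed <- xor(categories[1] == "biophysical", categories[2] == "biophysical")
    designated <- any(.irreversible_edges[, 1] == source &
                        .irreversible_edges[, 2] == target)
    edge_def(source, target, effect, mechanism,
             reversible = !mixed && !designated,
             rate_class = if (any(categories == "biophysical")) "biophysical" else "protein",
             provenance = provenance)
  }

  ed <- rbind(
    e("PolarizedSubstrateStiffness", "MembraneTension", "activate", "one_step",
      "stiffness gradient drives rear contractility, lowering rear tension"),
    e("ActoMyosinContractility", "MembraneTension", "activate", "one_step",
      "positive feedback: contractility further decreases rear tension"),
    e("MembraneTension", "Caveolae", "activate", "one_step",
      "decreased tension drives caveolae assembly (irreversible)"),
    e("Src", "Caveolae", "activate", "two_step",
      "Src phosphorylates Cav1 Y14, promoting caveolae formation"),
    e("Caveolae", "Src", "inhibit", "two_step",
      "pY14-Cav1 recruits/activates Csk, an inhibitor of Src"),
    e("Src", "p190RhoGAP", "activate", "two_step",
      "Src controls p190RhoGAP activity"),
    e("p190RhoGAP", "RhoA", "inhibit", "two_step",
      "GAP: accelerates RhoA GTP hydrolysis"),
    e("Caveolae", "Ect2", "activate", "two_step",
      "Ect2 recruited to the rear by caveolae"),
    e("Ect2", "RhoA", "activate", "two_step",
      "GEF: catalyses GDP->GTP exchange on RhoA"),
    e("RhoA", "ROCK1", "activate", "two_step", "RhoA effector kinase"),
    e("RhoA", "PKN2", "activate", "two_step", "RhoA effector kinase"),
    e("RhoA", "DRF", "activate", "two_step",
      "formins activated directly by RhoA"),
    e("ROCK1", "DRF", "activate", "two_step",
      "formins activated directly by ROCK1"),
    e("ROCK1", "LIMK", "activate", "two_step",
      "ROCK phosphorylates LIMK1 T508"),
    e("LIMK", "Cofilin", "inhibit", "two_step",
      "LIMK phosphorylates cofilin S3, abolishing depolymerising activity"),
    e("DRF", "Actin", "activate", "two_step",
      "formin-driven F-actin polymerisation"),
    e("Cofilin", "Actin", "inhibit", "two_step",
      "cofilin severs/disassembles F-actin"),
    e("ROCK1", "CPI17", "activate", "two_step",
      "CPI-17 T38 phosphorylation enhances MLCP inhibition"),
    e("PKN2", "CPI17", "activate", "two_step",
      "CPI-17 T38 phosphorylation enhances MLCP inhibition"),
    e("CPI17", "MLCP", "inhibit", "two_step",
      "phospho-CPI-17 inhibits myosin light chain phosphatase"),
    e("ROCK1", "pMLC", "activate", "one_step",
      "MLC phosphorylation (one-step: pMLC is a protein state)"),
    e("PKN2", "pMLC", "activate", "one_step",
      "MLC phosphorylation (one-step: pMLC is a protein state)"),
    e("MLCP", "pMLC", "inhibit", "one_step",
      "phosphatase opposes myosin phosphorylation"),
    e("Actin", "ActinAlignment", "activate", "one_step",
      "F-actin organises into aligned rear fibres"),
    e("ActinAlignment", "ActoMyosinContractility", "activate", "one_step",
      "aligned actin enables contractility (irreversible)"),
    e("pMLC", "ActoMyosinContractility", "activate", "one_step",
      "pMLC enables contractility (irreversible)"),
    e("ActoMyosinContractility", "RearRetraction", "activate", "one_step",
      "retraction requires contractility constantly"),
    e("ActinAlignment", "RearRetraction", "activate", "one_step",
      "retraction requires aligned actin constantly"))

  wiring_diagram(sp, ed)
}

#' Pool roster of a wiring diagram
#'
#' Pools are `<species>_a` (active), `<species>_i` (inactive), and one
#' transient binding complex `cx_<source>_<target>` per two-step edge.
#'
#' @param diagram an `rm_wiring`.
#' @return character vector of pool names in canonical order.
#' @export
pool_names <- function(diagram) {
  sp <- diagram$species$name
  two <- diagram$edges[diagram$edges$mechanism == "two_step", , drop = FALSE]
  c(rbind(paste0(sp, "_a"), paste0(sp, "_i")),
    if (nrow(two)) paste0("cx_", two$source, "_", two$target))
}

# Pools belonging to a species: active, inactive, and every complex in which
# it takes part (a complex counts in both endpoints' conservation sums).
species_pools <- function(diagram, species) {
  pools <- pool_names(diagram)
  cx <- grep("^cx_", pools, value = TRUE)
  parts <- strsplit(sub("^cx_", "", cx), "_", fixed = TRUE)
  involved <- cx[vapply(parts, function(p) species %in% p, logical(1))]
  list(active = paste0(species, "_a"), inactive = paste0(species, "_i"),
       bound = involved)
}

#' Validate a wiring diagram
#'
#' Checks the structural rules: unique species names, known edge endpoints,
#' exactly one clamped input, mechanism consistent with endpoint categories
#' (two-step for protein-protein except the pMLC target, one-step whenever a
#' biophysical entity is involved), reversibility restrictions, pMLC turnover
#' exemption, and initial amounts within `[0, total_moiety]` with moieties at
#' most 100.
#'
#' @param diagram an `rm_wiring`.
#' @return an `rm_validation` object; `$violations` is a `data.frame` with
#'   columns `rule` and `message` (zero rows when the diagram is valid).
#'   Violations are reported as data, never thrown.
#' @export
validate_wiring <- function(diagram) {
  v <- list()
  add <- function(rule, message) v[[length(v) + 1L]] <<- data.frame(
    rule = rule, message = message, stringsAsFactors = FALSE)
  sp <- diagram$species
  ed <- diagram$edges

  if (anyDuplicated(sp$name))
    add("unique_names", paste("duplicated species name:",
                              paste(unique(sp$name[duplicated(sp$name)]), collapse = ", ")))
  bad <- !(c(ed$source, ed$target) %in% sp$name)
  if (any(bad))
    add("unknown_endpoint", paste("edge endpoint names a missing species:",
                                  paste(unique(c(ed$source, ed$target)[bad]), collapse = ", ")))
  if (sum(sp$is_clamped_input) != 1L)
    add("single_input", sprintf("exactly one clamped input required, found %d",
                                sum(sp$is_clamped_input)))
  bad_ic <- sp$initial_active < 0 | sp$initial_active > sp$total_moiety |
    sp$total_moiety > 100
  for (nm in sp$name[bad_ic])
    add("moiety_bounds", sprintf(
      "%s: need 0 <= initial_active <= total_moiety <= 100", nm))
  if ("pMLC" %in% sp$name && sp$has_turnover[sp$name == "pMLC"])
    add("pmlc_turnover", "pMLC must be exempt from turnover")

  cat_of <- function(nm) sp$category[match(nm, sp$name)]
  for (k in seq_len(nrow(ed))) {
    src <- ed$source[k]; tgt <- ed$target[k]
    if (!(src %in% sp$name) || !(tgt %in% sp$name)) next
    cs <- cat_of(src); ct <- cat_of(tgt)
    biophys <- cs == "biophysical" || ct == "biophysical"
    lbl <- sprintf("%s -> %s", src, tgt)
    if (biophys && ed$mechanism[k] != "one_step")
      add("rule_v", sprintf("%s: edges involving a biophysical entity are one-step", lbl))
    if (!biophys && tgt != "pMLC" && ed$mechanism[k] != "two_step")
      add("rule_iv", sprintf(
        "%s: protein-protein edges are two-step (binding then conversion)", lbl))
    designated <- any(.irreversible_edges[, 1] == src & .irreversible_edges[, 2] == tgt)
    mixed <- xor(cs == "biophysical", ct == "biophysical")
    if (ed$reversible[k] && (designated || mixed))
      add("rule_vi", sprintf("%s: edge must be irreversible", lbl))
  }

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), message = character(), stringsAsFactors = FALSE)
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "rm_validation")
}

#' @export
print.rm_validation <- function(x, ...) {
  if (x$valid) cat("valid: no violations\n")
  else {
    cat(nrow(x$violations), "violation(s):\n")
    for (k in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s\n", x$violations$rule[k], x$violations$message[k]))
  }
  invisible(x)
}

stop_if_invalid <- function(diagram) {
  rep <- validate_wiring(diagram)
  if (!rep$valid)
    stop("invalid wiring diagram: [", rep$violations$rule[1], "] ",
         rep$violations$message[1], call. = FALSE)
  invisible(diagram)
}

#' Default initial conditions
#'
#' The unperturbed initial state: the clamped input (polarized substrate
#' stiffness) at its maximum of 100, Src half active (it has both activating
#' and inhibitory downstream roles but no upstream activator), the purely
#' inhibitory Cofilin and MLCP fully active, every other active pool 0, every
#' inactive pool the moiety remainder, and all binding complexes empty.
#'
#' @param diagram an `rm_wiring` (validated; invalid diagrams are rejected).
#' @return an `rm_state`: named numeric vector over [pool_names()] with a
#'   `wiring` attribute.
#' @export
default_initial_conditions <- function(diagram) {
  stop_if_invalid(diagram)
  pools <- pool_names(diagram)
  x <- stats::setNames(numeric(length(pools)), pools)
  sp <- diagram$species
  x[paste0(sp$name, "_a")] <- sp$initial_active
  x[paste0(sp$name, "_i")] <- sp$total_moiety - sp$initial_active
  structure(x, wiring = diagram, class = "rm_state")
}

#' Moiety conservation check for a state
#'
#' The clamped input is exempt: it is a boundary species whose pools events
#' reassign freely.
#'
#' @param state an `rm_state`.
#' @param tol relative tolerance on each species' moiety total.
#' @return logical; attribute `worst` holds the largest relative deviation.
#' @export
check_conservation <- function(state, tol = 1e-6) {
  diagram <- attr(state, "wiring")
  names_checked <- setdiff(diagram$species$name, diagram$input_species)
  dev <- vapply(names_checked, function(nm) {
    p <- species_pools(diagram, nm)
    tot <- diagram$species$total_moiety[diagram$species$name == nm]
    tot <- attr(state, "moiety_override")[[nm]] %||% tot
    abs(sum(state[c(p$active, p$inactive, p$bound)]) - tot) / max(tot, 1)
  }, numeric(1))
  structure(all(dev <= tol), worst = max(dev))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' In-silico knockdown of a species
#'
#' Rescales a species' conserved moiety to `fraction` of its original total,
#' scaling the active and inactive pools proportionally (a 12% knockdown of
#' RhoA leaves 12 units of RhoA moiety in total). The species must be free of
#' bound complexes in the given state, otherwise the rescale would be
#' ambiguous.
#'
#' @param state an `rm_state`.
#' @param species species name.
#' @param fraction proportion of the moiety retained, in `[0, 1]`.
#' @return the modified `rm_state`; knockdowns compose multiplicatively.
#' @export
apply_knockdown <- function(state, species, fraction) {
  diagram <- attr(state, "wiring")
  if (!species %in% diagram$species$name)
    stop("unknown species: ", species)
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  p <- species_pools(diagram, species)
  if (any(state[p$bound] != 0))
    stop("knockdown of ", species,
         " with nonzero bound pools is ambiguous; apply at t = 0")
  state[c(p$active, p$inactive)] <- state[c(p$active, p$inactive)] * fraction
  ov <- attr(state, "moiety_override") %||% list()
  base <- ov[[species]] %||%
    diagram$species$total_moiety[diagram$species$name == species]
  ov[[species]] <- base * fraction
  attr(state, "moiety_override") <- ov
  state
}
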