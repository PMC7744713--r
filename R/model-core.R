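#' Construct a constraint-based metabolic model
#'
#' The container for all flux computation: stoichiometry, flux bounds,
#' pathway (subsystem) labels, and gene-protein-reaction rules. Bounds are
#' in mmol gDW^-1 h^-1 throughout; exchange reactions follow the standard
#' convention negative flux = uptake, positive = secretion.
#'
#' @param model_id character scalar.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `subsystem`,
#'   `lower_bound`, `upper_bound`, `gpr` (rule text, `""` when none),
#'   `objective_coefficient`.
#' @param genes character vector of gene ids.
#' @param S stoichiometric matrix (metabolites x reactions); coerced to a
#'   sparse `Matrix::dgCMatrix` with dimnames taken from `metabolites$id`
#'   and `reactions$id`.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, metabolites, reactions, genes, S) {
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$name[is.na(reactions$name)] <- ""
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  m <- structure(
    list(model_id = model_id,
         metabolites = metabolites,
         reactions = reactions,
         genes = as.character(genes),
         S = S),
    class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model's invariants
#'
#' Checks bound ordering, id uniqueness, S dimensions, GPR well-formedness
#' and gene coverage. Violations always raise an error (never a warning).
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly usable in a pipeline (returned unchanged).
#' @export
validate_model <- function(model) {
  rxn <- model$reactions
  met <- model$metabolites
  if (anyDuplicated(rxn$id))
    stop("duplicate reaction id(s): ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(met$id))
    stop("duplicate metabolite id(s): ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "), call. = FALSE)
  bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  if (length(bad))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (ncol(model$S) != nrow(rxn))
    stop("S has ", ncol(model$S), " columns but the model has ",
         nrow(rxn), " reactions", call. = FALSE)
  if (nrow(model$S) != nrow(met))
    stop("S has ", nrow(model$S), " rows but the model has ",
         nrow(met), " metabolites", call. = FALSE)
  for (i in seq_len(nrow(rxn))) {
    tree <- tryCatch(parse_gpr(rxn$gpr[i]), error = function(e)
      stop("reaction '", rxn$id[i], "': ", conditionMessage(e), call. = FALSE))
    missing_g <- setdiff(gpr_genes(tree), model$genes)
    if (length(missing_g))
      stop("reaction '", rxn$id[i], "' references gene(s) not in the model: ",
           paste(missing_g, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$model_id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   genes: ", length(x$genes), "\n", sep = "")
  invisible(x)
}

#' Number of reactions in a model
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' Look up flux bounds for a reaction
#' @param model a `metabolic_model`.
#' @param reaction_id reaction identifier.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
reaction_bounds <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id '", reaction_id, "'", call. = FALSE)
  c(lower = model$reactions$lower_bound[i], upper = model$reactions$upper_bound[i])
}

# SBML default when a file omits bounds
.DEFAULT_BOUND <- 1000

#' Read a metabolic model from SBML (Level 3 + FBC) or JSON
#'
#' The JSON dialect is the cobra-style schema: top-level `id`,
#' `metabolites` (objects with `id`, `name`, `compartment`), `reactions`
#' (objects with `id`, `name`, `metabolites` map of stoichiometries,
#' `lower_bound`, `upper_bound`, `gene_reaction_rule`, `subsystem`,
#' `objective_coefficient`) and `genes` (objects with `id`). For SBML,
#' flux bounds are resolved through FBC bound parameters, GPRs through
#' `fbc:geneProductAssociation`, and subsystems through SBML groups.
#' Missing subsystems become `""`, missing GPRs `""`, missing bounds the
#' conventional +/-1000 default. Unknown annotations are ignored.
#'
#' @param path file path.
#' @param format `"sbml_fbc"` or `"json"`; default guessed from extension.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("guess", "sbml_fbc", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml_fbc"
  }
  switch(format, json = read_model_json(path), sbml_fbc = read_model_sbml(path))
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("unparseable JSON model '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  for (fld in c("metabolites", "reactions"))
    if (is.null(doc[[fld]])) stop("JSON model missing '", fld, "' element", call. = FALSE)
  met <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, character(1)),
    name = vapply(doc$metabolites, function(m) m$name %||% "", character(1)),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "", character(1)),
    stringsAsFactors = FALSE)
  num_or <- function(x, d) if (is.null(x)) d else as.numeric(x)
  rxn <- data.frame(
    id = vapply(doc$reactions, function(r) r$id, character(1)),
    name = vapply(doc$reactions, function(r) r$name %||% "", character(1)),
    subsystem = vapply(doc$reactions, function(r) r$subsystem %||% "", character(1)),
    lower_bound = vapply(doc$reactions, function(r) num_or(r$lower_bound, -.DEFAULT_BOUND), numeric(1)),
    upper_bound = vapply(doc$reactions, function(r) num_or(r$upper_bound, .DEFAULT_BOUND), numeric(1)),
    gpr = vapply(doc$reactions, function(r) r$gene_reaction_rule %||% "", character(1)),
    objective_coefficient = vapply(doc$reactions, function(r) num_or(r$objective_coefficient, 0), numeric(1)),
    stringsAsFactors = FALSE)
  S <- Matrix::Matrix(0, nrow(met), nrow(rxn), sparse = TRUE)
  rownames(S) <- met$id
  for (j in seq_along(doc$reactions)) {
    st <- doc$reactions[[j]]$metabolites
    for (mid in names(st)) {
      if (!mid %in% met$id)
        stop("reaction '", rxn$id[j], "' references unknown metabolite '", mid, "'", call. = FALSE)
      S[mid, j] <- as.numeric(st[[mid]])
    }
  }
  genes <- if (is.null(doc$genes)) character(0) else
    vapply(doc$genes, function(g) if (is.list(g)) g$id else as.character(g), character(1))
  metabolic_model(doc$id %||% basename(path), met, rxn, genes, S)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable SBML file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("unparseable SBML file '", path, "': no <model> element", call. = FALSE)
  attr1 <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    ifelse(is.na(v), "", v)
  }
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  met <- data.frame(id = xml2::xml_attr(sp, "id"),
                    name = attr1(sp, "name"),
                    compartment = attr1(sp, "compartment"),
                    stringsAsFactors = FALSE)
  # FBC flux-bound parameters
  par <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")), xml2::xml_attr(par, "id"))
  lookup_bound <- function(ref, default) {
    if (is.na(ref) || !nzchar(ref)) return(default)
    if (!ref %in% names(pval))
      stop("SBML flux bound parameter '", ref, "' not defined", call. = FALSE)
    pval[[ref]]
  }
  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  gpr_from_node <- function(node) {
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    if (inherits(assoc, "xml_missing")) return("")
    kids <- xml2::xml_children(assoc)
    if (length(kids) == 0L) return("")
    deparse_gpr(sbml_assoc_tree(kids[[1]], ns))
  }
  n_rx <- length(rx_nodes)
  rxn <- data.frame(id = xml2::xml_attr(rx_nodes, "id"),
                    name = attr1(rx_nodes, "name"),
                    subsystem = "",
                    lower_bound = NA_real_, upper_bound = NA_real_,
                    gpr = "", objective_coefficient = 0,
                    stringsAsFactors = FALSE)
  S <- Matrix::Matrix(0, nrow(met), n_rx, sparse = TRUE)
  rownames(S) <- met$id
  for (j in seq_len(n_rx)) {
    node <- rx_nodes[[j]]
    rev_ok <- identical(xml2::xml_attr(node, "reversible"), "true")
    rxn$lower_bound[j] <- lookup_bound(xml2::xml_attr(node, "fbc:lowerFluxBound", ns),
                                       if (rev_ok) -.DEFAULT_BOUND else 0)
    rxn$upper_bound[j] <- lookup_bound(xml2::xml_attr(node, "fbc:upperFluxBound", ns),
                                       .DEFAULT_BOUND)
    rxn$gpr[j] <- gpr_from_node(node)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./s:", side, "/s:speciesReference"), ns)
      for (ref in refs) {
        mid <- xml2::xml_attr(ref, "species")
        if (!mid %in% met$id)
          stop("reaction '", rxn$id[j], "' references unknown species '", mid, "'", call. = FALSE)
        stoich <- xml2::xml_attr(ref, "stoichiometry")
        stoich <- if (is.na(stoich)) 1 else as.numeric(stoich)
        S[mid, j] <- S[mid, j] + sgn * stoich
      }
    }
  }
  # objective coefficients from the active FBC objective
  obj <- xml2::xml_find_all(mdl, ".//fbc:listOfObjectives/fbc:objective[1]/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  for (o in obj) {
    rid <- xml2::xml_attr(o, "fbc:reaction", ns)
    coef <- as.numeric(xml2::xml_attr(o, "fbc:coefficient", ns))
    rxn$objective_coefficient[match(rid, rxn$id)] <- coef
  }
  # subsystems from SBML groups (member idRef -> group name)
  grp <- xml2::xml_find_all(mdl, ".//g:listOfGroups/g:group", ns)
  for (gnode in grp) {
    gname <- xml2::xml_attr(gnode, "name")
    if (is.na(gname)) gname <- xml2::xml_attr(gnode, "id")
    members <- xml2::xml_attr(xml2::xml_find_all(gnode, ".//g:member", ns), "idRef")
    rxn$subsystem[rxn$id %in% members] <- gname
  }
  genes <- xml2::xml_attr(
    xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns), "id")
  # gene ids in rules use the geneProduct label where present
  glab <- xml2::xml_attr(
    xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns), "label")
  if (length(glab) && !anyNA(glab)) genes <- glab
  metabolic_model(xml2::xml_attr(mdl, "id") %||% basename(path), met, rxn, genes, S)
}

sbml_assoc_tree <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProduct") {
    ref <- xml2::xml_attr(node, "fbc:geneProduct", ns)
    # resolve to the label used as the public gene id
    root <- xml2::xml_root(node)
    gp <- xml2::xml_find_first(root, sprintf(".//fbc:geneProduct[@fbc:id='%s']", ref), ns)
    lab <- if (!inherits(gp, "xml_missing")) xml2::xml_attr(gp, "label") else NA
    return(list(op = "gene", id = if (!is.na(lab)) lab else ref))
  }
  if (nm %in% c("and", "or")) {
    return(list(op = nm,
                args = lapply(xml2::xml_children(node), sbml_assoc_tree, ns = ns)))
  }
  stop("unsupported geneProductAssociation node <", nm, ">", call. = FALSE)
}

#' Write a model to the cobra-style JSON dialect
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    col <- model$S[, j]
    nz <- which(col != 0)
    list(id = r$id, name = r$name,
         metabolites = as.list(stats::setNames(col[nz], rownames(model$S)[nz])),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr, subsystem = r$subsystem,
         objective_coefficient = r$objective_coefficient)
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  doc <- list(id = model$model_id, metabolites = mets, reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a model as SBML Level 3 + FBC v2 (round-trip subset)
#'
#' Emits species, reactions with FBC bound parameters, gene products,
#' gene associations, the biomass objective, and subsystem groups —
#' the subset [read_model()] understands.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rxn <- model$reactions
  comps <- unique(model$metabolites$compartment)
  comps[!nzchar(comps)] <- "c"
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1" ',
           'level="3" version="1" fbc:required="false" groups:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$model_id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', unique(comps)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    cc <- if (nzchar(m$compartment)) m$compartment else "c"
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m$id), esc(m$name), esc(cc)))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  bnd_par <- character(nrow(rxn) * 2)
  for (j in seq_len(nrow(rxn))) {
    bnd_par[2 * j - 1] <- sprintf('      <parameter id="%s_lb" value="%s" constant="true"/>',
                                  rxn$id[j], format(rxn$lower_bound[j], digits = 17))
    bnd_par[2 * j] <- sprintf('      <parameter id="%s_ub" value="%s" constant="true"/>',
                              rxn$id[j], format(rxn$upper_bound[j], digits = 17))
  }
  lines <- c(lines, bnd_par, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    col <- model$S[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s_lb" fbc:upperFluxBound="%s_ub">',
      esc(rxn$id[j]), esc(rxn$name[j]),
      if (rxn$lower_bound[j] < 0) "true" else "false", rxn$id[j], rxn$id[j]))
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         rownames(model$S)[reac], format(-col[reac], digits = 17)),
                 '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         rownames(model$S)[prod], format(col[prod], digits = 17)),
                 '        </listOfProducts>')
    }
    if (nzchar(rxn$gpr[j])) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 sbml_assoc_xml(parse_gpr(rxn$gpr[j]), indent = "          "),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (length(model$genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                       gsub("[^A-Za-z0-9_]", "_", model$genes), esc(model$genes)),
               '    </fbc:listOfGeneProducts>')
  }
  wobj <- which(rxn$objective_coefficient != 0)
  if (length(wobj)) {
    lines <- c(lines,
               '    <fbc:listOfObjectives fbc:activeObjective="obj">',
               '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
               '        <fbc:listOfFluxObjectives>',
               sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
                       rxn$id[wobj], format(rxn$objective_coefficient[wobj], digits = 17)),
               '        </fbc:listOfFluxObjectives>',
               '      </fbc:objective>',
               '    </fbc:listOfObjectives>')
  }
  subs <- unique(rxn$subsystem[nzchar(rxn$subsystem)])
  if (length(subs)) {
    lines <- c(lines, '    <groups:listOfGroups>')
    for (k in seq_along(subs)) {
      members <- rxn$id[rxn$subsystem == subs[k]]
      lines <- c(lines,
                 sprintf('      <groups:group groups:id="grp%d" groups:name="%s" groups:kind="partonomy">',
                         k, esc(subs[k])),
                 '        <groups:listOfMembers>',
                 sprintf('          <groups:member groups:idRef="%s"/>', members),
                 '        </groups:listOfMembers>',
                 '      </groups:group>')
    }
    lines <- c(lines, '    </groups:listOfGroups>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

sbml_assoc_xml <- function(tree, indent) {
  if (tree$op == "gene")
    return(sprintf('%s<fbc:geneProduct fbc:geneProduct="G_%s"/>', indent,
                   gsub("[^A-Za-z0-9_]", "_", tree$id)))
  c(sprintf('%s<fbc:%s>', indent, tree$op),
    unlist(lapply(tree$args, sbml_assoc_xml, indent = paste0(indent, "  "))),
    sprintf('%s</fbc:%s>', indent, tree$op))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
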