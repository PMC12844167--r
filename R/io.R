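# Model readers/writers: a JSON dialect mirroring SBML-FBC content, and a
# minimal SBML Level 3 + FBC v2 subset (species, compartments, parameters as
# flux bounds, GPR association trees, objective; subsystem and member tag
# carried in reaction notes).

#' Read a metabolic model from file
#'
#' @param path file path.
#' @param format `"json"` or `"sbml-fbc"`; default guesses from the extension
#'   (`.json` vs `.xml`/`.sbml`).
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml-fbc")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml-fbc"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, json = .read_model_json(path), `sbml-fbc` = .read_model_sbml(path))
}

#' Write a metabolic model to file
#'
#' Round-trips with [read_model()]: ids, bounds, stoichiometry, GPR strings
#' and subsystems are preserved.
#'
#' @param model a `metabolic_model`.
#' @param path destination path.
#' @param format `"json"` or `"sbml-fbc"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml-fbc")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml-fbc"
  }
  switch(format,
         json = .write_model_json(model, path),
         `sbml-fbc` = .write_model_sbml(model, path))
  invisible(path)
}

# ---- JSON dialect ----

.read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("id", "reactions", "metabolites", "compartments"))
    if (is.null(j[[f]])) stop("malformed JSON model: missing field '", f, "'")
  comp <- data.frame(id = names(j$compartments),
                     name = unlist(j$compartments, use.names = FALSE),
                     stringsAsFactors = FALSE)
  g <- function(x, f, d) if (is.null(x[[f]])) d else x[[f]]
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed JSON model: metabolite without id")
    data.frame(id = m$id, name = g(m, "name", ""), compartment = g(m, "compartment", NA),
               formula = g(m, "formula", NA), charge = g(m, "charge", NA),
               member_tag = g(m, "member_tag", NA), stringsAsFactors = FALSE)
  }))
  genes <- if (length(j$genes)) do.call(rbind, lapply(j$genes, function(x)
    data.frame(id = x$id, name = g(x, "name", ""), stringsAsFactors = FALSE))) else NULL
  rx <- do.call(rbind, lapply(j$reactions, function(r) {
    if (is.null(r$id)) stop("malformed JSON model: reaction without id")
    if (is.null(r$lower_bound) || is.null(r$upper_bound))
      stop("malformed JSON model: reaction '", r$id, "' lacks bounds")
    data.frame(id = r$id, name = g(r, "name", ""),
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               gpr = g(r, "gene_reaction_rule", NA),
               subsystem = g(r, "subsystem", NA),
               member_tag = g(r, "member_tag", NA), stringsAsFactors = FALSE)
  }))
  rx$gpr[!is.na(rx$gpr) & !nzchar(rx$gpr)] <- NA
  stoich <- do.call(rbind, lapply(j$reactions, function(r) {
    if (is.null(r$metabolites) || !length(r$metabolites))
      stop("malformed JSON model: reaction '", r$id, "' has empty stoichiometry")
    data.frame(reaction = r$id, metabolite = names(r$metabolites),
               coefficient = unlist(r$metabolites, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  metabolic_model(id = j$id, compartments = comp, metabolites = mets,
                  reactions = rx, stoich = stoich, genes = genes,
                  objective = j$objective)
}

.write_model_json <- function(model, path) {
  out <- .model_json_list(model)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

.model_json_list <- function(model) {
  drop_na <- function(x) x[!vapply(x, function(v) is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  sx <- split(model$stoich, model$stoich$reaction)
  rxl <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- sx[[r$id]]
    drop_na(list(id = r$id, name = r$name,
                 metabolites = as.list(stats::setNames(s$coefficient, s$metabolite)),
                 lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                 gene_reaction_rule = r$gpr, subsystem = r$subsystem,
                 member_tag = r$member_tag))
  })
  metl <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    drop_na(list(id = m$id, name = m$name, compartment = m$compartment,
                 formula = m$formula, charge = m$charge, member_tag = m$member_tag))
  })
  list(id = model$id,
       objective = model$objective,
       compartments = as.list(stats::setNames(model$compartments$name,
                                              model$compartments$id)),
       metabolites = metl,
       genes = lapply(seq_len(nrow(model$genes)), function(i)
         list(id = model$genes$id[i], name = model$genes$name[i])),
       reactions = rxl)
}

#' Write a joint model (with member and interspace registries) as JSON
#' @param joint a `joint_model`.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_joint_model <- function(joint, path) {
  out <- .model_json_list(joint)
  out$members <- joint$members
  out$interspace <- joint$interspace
  out$lumen_exchanges <- joint$lumen_exchanges
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read a joint model written by [write_joint_model()]
#' @param path the `.json` path.
#' @return a `joint_model`.
#' @export
read_joint_model <- function(path) {
  m <- .read_model_json(path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(j$members) || is.null(j$interspace))
    stop("'", path, "' is not a joint-model file (missing registries)")
  m$members <- as.data.frame(j$members, stringsAsFactors = FALSE)
  m$interspace <- as.data.frame(j$interspace, stringsAsFactors = FALSE)
  m$lumen_exchanges <- as.character(j$lumen_exchanges)
  class(m) <- c("joint_model", class(m))
  m
}

# ---- SBML L3 + FBC v2 subset ----

.SBML_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sid_check <- function(ids, what) {
  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)
  if (any(bad))
    stop("cannot write SBML: ", what, " id(s) not SId-conforming: ",
         paste(utils::head(ids[bad], 5), collapse = ", "),
         " (use the JSON format for such ids)")
}

.xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.write_model_sbml <- function(model, path) {
  .sid_check(model$metabolites$id, "metabolite")
  .sid_check(model$reactions$id, "reaction")
  .sid_check(model$compartments$id, "compartment")
  if (nrow(model$genes)) .sid_check(model$genes$id, "gene")

  fmt <- function(v) vapply(v, function(b) sprintf("%.17g", b), character(1))
  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), fmt(bounds))
  pref <- function(v) unname(pid[fmt(v)])

  L <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
         sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
                 .SBML_CORE, .SBML_FBC),
         sprintf('  <model id="%s" fbc:strict="true">', .xesc(model$id)))
  L <- c(L, "    <listOfCompartments>",
         sprintf('      <compartment id="%s" name="%s" constant="true"/>',
                 model$compartments$id, .xesc(model$compartments$name)),
         "    </listOfCompartments>")
  met_extra <- ifelse(is.na(model$metabolites$member_tag), "",
                      sprintf(' sboTerm="SBO:0000247"'))
  L <- c(L, "    <listOfSpecies>",
         sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
                        'hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s%s/>'),
                 model$metabolites$id, .xesc(model$metabolites$name),
                 model$metabolites$compartment,
                 ifelse(is.na(model$metabolites$formula), "",
                        sprintf(' fbc:chemicalFormula="%s"', model$metabolites$formula)),
                 ifelse(is.na(model$metabolites$charge), "",
                        sprintf(' fbc:charge="%d"', as.integer(model$metabolites$charge)))),
         "    </listOfSpecies>")
  L <- c(L, "    <listOfParameters>",
         sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                 unname(pid), format(bounds, digits = 17)),
         "    </listOfParameters>")

  sx <- split(model$stoich, model$stoich$reaction)
  L <- c(L, "    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- sx[[r$id]]
    L <- c(L, sprintf(paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
                             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
                      r$id, .xesc(r$name), tolower(r$lower_bound < 0),
                      pref(r$lower_bound), pref(r$upper_bound)))
    notes <- character()
    if (!is.na(r$subsystem)) notes <- c(notes, sprintf("<p>SUBSYSTEM: %s</p>", .xesc(r$subsystem)))
    if (!is.na(r$member_tag)) notes <- c(notes, sprintf("<p>MEMBER_TAG: %s</p>", .xesc(r$member_tag)))
    if (length(notes))
      L <- c(L, '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
             paste0("          ", notes), "        </body></notes>")
    reac <- s[s$coefficient < 0, , drop = FALSE]
    prod <- s[s$coefficient > 0, , drop = FALSE]
    if (nrow(reac))
      L <- c(L, "        <listOfReactants>",
             sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                     reac$metabolite, format(-reac$coefficient, digits = 17)),
             "        </listOfReactants>")
    if (nrow(prod))
      L <- c(L, "        <listOfProducts>",
             sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                     prod$metabolite, format(prod$coefficient, digits = 17)),
             "        </listOfProducts>")
    if (!is.na(r$gpr) && nzchar(r$gpr))
      L <- c(L, "        <fbc:geneProductAssociation>",
             .gpr_to_sbml(parse_gpr(r$gpr), indent = "          "),
             "        </fbc:geneProductAssociation>")
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>")
  if (nrow(model$genes))
    L <- c(L, "    <fbc:listOfGeneProducts>",
           sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                   model$genes$id, model$genes$id),
           "    </fbc:listOfGeneProducts>")
  if (!is.null(model$objective))
    L <- c(L, '    <fbc:listOfObjectives fbc:activeObjective="obj">',
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           '        <fbc:listOfFluxObjectives>',
           sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
                   model$objective),
           '        </fbc:listOfFluxObjectives>',
           '      </fbc:objective>',
           '    </fbc:listOfObjectives>')
  L <- c(L, "  </model>", "</sbml>")
  writeLines(L, path)
}

.gpr_to_sbml <- function(tree, indent) {
  if (tree$op == "gene")
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', indent, tree$gene))
  tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
  c(sprintf("%s<%s>", indent, tag),
    unlist(lapply(tree$args, .gpr_to_sbml, indent = paste0(indent, "  "))),
    sprintf("%s</%s>", indent, tag))
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path, "': ",
                                           conditionMessage(e)))
  root <- xml2::xml_ns_strip(doc)   # work positionally; fbc attrs keep prefix in names
  if (xml2::xml_name(root) != "sbml") stop("not an SBML document: ", path)
  lvl <- xml2::xml_attr(root, "level")
  if (is.na(lvl) || lvl != "3")
    stop("unsupported SBML level '", lvl, "': only Level 3 + FBC is supported")
  mdl <- xml2::xml_find_first(root, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML file has no <model> element")

  strip <- function(x, p) sub(paste0("^", p), "", x)
  comp_nodes <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  comp <- data.frame(id = xml2::xml_attr(comp_nodes, "id"),
                     name = ifelse(is.na(xml2::xml_attr(comp_nodes, "name")), "",
                                   xml2::xml_attr(comp_nodes, "name")),
                     stringsAsFactors = FALSE)
  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "", xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "charge"))),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  n <- length(rx_nodes)
  if (n == 0) stop("SBML model contains no reactions")
  rid <- strip(xml2::xml_attr(rx_nodes, "id"), "R_")
  lb_ref <- xml2::xml_attr(rx_nodes, "lowerFluxBound")
  ub_ref <- xml2::xml_attr(rx_nodes, "upperFluxBound")
  nob <- is.na(lb_ref) | is.na(ub_ref)
  if (any(nob))
    stop("SBML reactions lacking FBC flux bounds: ",
         paste(utils::head(rid[nob], 10), collapse = ", "))
  miss <- setdiff(unique(c(lb_ref, ub_ref)), names(pvals))
  if (length(miss))
    stop("SBML flux-bound parameters not declared: ", paste(miss, collapse = ", "))

  note_field <- function(node, key) {
    ps <- xml2::xml_text(xml2::xml_find_all(node, ".//notes//p"))
    hit <- grep(paste0("^", key, ": "), ps, value = TRUE)
    if (length(hit)) sub(paste0("^", key, ": "), "", hit[1]) else NA_character_
  }
  rx <- data.frame(id = rid,
                   name = ifelse(is.na(xml2::xml_attr(rx_nodes, "name")), "",
                                 xml2::xml_attr(rx_nodes, "name")),
                   lower_bound = unname(pvals[lb_ref]),
                   upper_bound = unname(pvals[ub_ref]),
                   gpr = NA_character_, subsystem = NA_character_,
                   member_tag = NA_character_, stringsAsFactors = FALSE)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    rx$subsystem[i] <- note_field(node, "SUBSYSTEM")
    rx$member_tag[i] <- note_field(node, "MEMBER_TAG")
    ga <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']/*")
    if (!inherits(ga, "xml_missing"))
      rx$gpr[i] <- .gpr_deparse(parse_gpr(.sbml_gpr_string(ga)))
    re <- xml2::xml_find_all(node, ".//listOfReactants/speciesReference")
    pr <- xml2::xml_find_all(node, ".//listOfProducts/speciesReference")
    s <- data.frame(
      reaction = rid[i],
      metabolite = strip(c(xml2::xml_attr(re, "species"), xml2::xml_attr(pr, "species")), "M_"),
      coefficient = c(-as.numeric(xml2::xml_attr(re, "stoichiometry")),
                      as.numeric(xml2::xml_attr(pr, "stoichiometry"))),
      stringsAsFactors = FALSE)
    if (!nrow(s)) stop("SBML reaction '", rid[i], "' has empty stoichiometry")
    stoich[[i]] <- s
  }
  gp <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  genes <- if (length(gp)) data.frame(id = strip(xml2::xml_attr(gp, "id"), "G_"),
                                      name = "", stringsAsFactors = FALSE) else NULL
  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  objective <- if (!inherits(fo, "xml_missing"))
    strip(xml2::xml_attr(fo, "reaction"), "R_") else NULL
  metabolic_model(id = xml2::xml_attr(mdl, "id"), compartments = comp,
                  metabolites = mets, reactions = rx,
                  stoich = do.call(rbind, stoich), genes = genes,
                  objective = objective)
}

.sbml_gpr_string <- function(node) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef")
    return(sub("^G_", "", xml2::xml_attr(node, "geneProduct")))
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, .sbml_gpr_string, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}
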