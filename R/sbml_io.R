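# Model and environment I/O.
#
# SBML support covers the subset genome-scale bacterial reconstructions
# actually use for flux balance analysis: species with compartments,
# reactions with stoichiometry, flux bounds (fbc parameters, legacy
# kineticLaw LOWER_BOUND/UPPER_BOUND parameters, or reversibility
# defaults), and the fbc objective. Written files are SBML Level 3
# Version 1 with the fbc v2 package.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.DEFAULT_COMPARTMENT_MAP <- c(e = "extracellular", c = "cytoplasm", p = "periplasm")

#' Read a metabolic model from SBML
#'
#' Parses SBML Level 2/3. Flux bounds are taken from fbc
#' `lowerFluxBound`/`upperFluxBound` parameter references when present,
#' else from `LOWER_BOUND`/`UPPER_BOUND` kineticLaw parameters, else from
#' the `reversible` flag (`[-1000, 1000]` vs `[0, 1000]`). The biomass
#' reaction is the active fbc objective when declared, else the first
#' reaction whose id or name matches `biomass_pattern`. The returned model
#' still contains any exchange reaction columns and has an empty default
#' environment; pass it through [canonicalize_model()] before analysis.
#'
#' @param path SBML file path.
#' @param biomass_pattern case-insensitive regex fallback for biomass
#'   detection.
#' @param compartment_map named character mapping SBML compartment ids to
#'   `"extracellular"`, `"cytoplasm"`, `"periplasm"`.
#' @return A [metabolic_model()] (pre-canonicalization).
#' @export
read_sbml_model <- function(path, biomass_pattern = "biomass",
                            compartment_map = .DEFAULT_COMPARTMENT_MAP) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("read_sbml_model: cannot parse '", path, "': ", conditionMessage(e))
  })
  model_node <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) {
    stop("read_sbml_model: no <model> element in ", path)
  }
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- basename(path)

  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  if (length(sp_nodes) == 0) stop("read_sbml_model: no species in ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  unknown <- setdiff(unique(sp_comp), names(compartment_map))
  if (length(unknown)) {
    stop("read_sbml_model: unknown compartment code '",
         paste(unknown, collapse = "', '"), "' in ", path)
  }
  compounds <- data.frame(id = sp_id, name = sp_name,
                          compartment = unname(compartment_map[sp_comp]),
                          stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(doc, "/*/*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  attr_like <- function(node, what) {
    at <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", what, "$"), names(at))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }

  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop("read_sbml_model: no reactions in ", path)
  reactions <- list()
  for (node in rx_nodes) {
    rid <- xml2::xml_attr(node, "id")
    st <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./*[local-name()='", side,
                                              "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + sgn * coef
      }
    }
    lo_ref <- attr_like(node, "lowerFluxBound")
    hi_ref <- attr_like(node, "upperFluxBound")
    if (!is.na(lo_ref) && !is.na(hi_ref)) {
      lb <- par_val[[lo_ref]]; ub <- par_val[[hi_ref]]
    } else {
      kl <- xml2::xml_find_all(node, ".//*[local-name()='parameter' or local-name()='localParameter']")
      kl_id <- xml2::xml_attr(kl, "id")
      kl_v <- as.numeric(xml2::xml_attr(kl, "value"))
      if ("LOWER_BOUND" %in% kl_id && "UPPER_BOUND" %in% kl_id) {
        lb <- kl_v[match("LOWER_BOUND", kl_id)]
        ub <- kl_v[match("UPPER_BOUND", kl_id)]
      } else {
        rev <- identical(xml2::xml_attr(node, "reversible"), "true")
        lb <- if (rev) -1000 else 0
        ub <- 1000
      }
    }
    reactions[[rid]] <- list(stoich = st, lb = lb, ub = ub)
  }

  obj_ref <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  biomass_id <- if (!inherits(obj_ref, "xml_missing")) {
    attr_like(obj_ref, "reaction")
  } else NA_character_
  if (is.na(biomass_id)) {
    rx_ids <- names(reactions)
    rx_names <- vapply(rx_nodes, function(n) {
      nm <- xml2::xml_attr(n, "name"); if (is.na(nm)) "" else nm
    }, character(1))
    hit <- which(grepl(biomass_pattern, rx_ids, ignore.case = TRUE) |
                   grepl(biomass_pattern, rx_names, ignore.case = TRUE))
    if (length(hit) == 0) {
      stop("read_sbml_model: no fbc objective and no reaction matching /",
           biomass_pattern, "/i in ", path)
    }
    biomass_id <- rx_ids[hit[1]]
  }
  model_from_reactions(model_id, compounds, reactions, biomass_id,
                       default_env = growth_env())
}

#' Canonicalize a model: fold exchange reactions into environment bounds
#'
#' Exchange reactions (a single extracellular metabolite, no other
#' participants) are removed; their flux bounds become the metabolite's
#' default-environment bounds on the net-change vector. With the
#' metabolite as the sole reactant (coefficient -1, the usual convention)
#' the bounds transfer directly: an uptake allowance of 10 (`lb = -10`)
#' becomes `l_c = -10`. Reactions whose id marks them as exchanges
#' (`exchange_pattern`) but that touch more than one metabolite, and
#' exchanges of intracellular metabolites, are errors. Sink/demand
#' reactions (single intracellular metabolite) are rejected unless
#' `drop_sinks = TRUE` because internal accumulation is forbidden.
#'
#' @param raw a [read_sbml_model()] result (or any model with exchange
#'   columns).
#' @param exchange_pattern regex on reaction ids marking intended
#'   exchanges.
#' @param drop_sinks drop sink/demand reactions silently instead of
#'   erroring.
#' @return A [metabolic_model()] with no exchange columns and a populated
#'   default environment.
#' @export
canonicalize_model <- function(raw, exchange_pattern = "^EX_",
                               drop_sinks = FALSE) {
  stopifnot(inherits(raw, "metabolic_model"))
  S <- raw$S
  ext <- is_extracellular(raw)
  nz_count <- Matrix::colSums(S != 0)
  lower <- raw$default_env$lower
  upper <- raw$default_env$upper
  drop <- logical(ncol(S))
  for (j in seq_len(ncol(S))) {
    rid <- colnames(S)[j]
    if (rid == raw$biomass_id) next  # biomass legitimately consumes net mass
    marked <- grepl(exchange_pattern, rid, ignore.case = TRUE)
    if (nz_count[j] != 1) {
      if (marked) {
        stop("canonicalize_model: reaction ", rid, " is marked as an ",
             "exchange but touches ", nz_count[j], " metabolites")
      }
      next
    }
    ridx <- which(S[, j] != 0)
    coef <- S[ridx, j]
    if (!ext[ridx]) {
      if (marked) {
        stop("canonicalize_model: exchange ", rid,
             " touches intracellular metabolite ", rownames(S)[ridx])
      }
      if (drop_sinks) { drop[j] <- TRUE; next }
      stop("canonicalize_model: sink/demand reaction ", rid, " on ",
           rownames(S)[ridx], " is not supported (internal accumulation ",
           "is forbidden); use drop_sinks = TRUE to drop it")
    }
    if (abs(coef) != 1) {
      stop("canonicalize_model: exchange ", rid,
           " has non-unit stoichiometry ", coef)
    }
    cid <- rownames(S)[ridx]
    # with coef -1, net extracellular change c equals the exchange flux
    lo <- if (coef == -1) raw$lb[[j]] else -raw$ub[[j]]
    hi <- if (coef == -1) raw$ub[[j]] else -raw$lb[[j]]
    lower[cid] <- (if (cid %in% names(lower)) lower[[cid]] else 0) + min(lo, 0)
    upper[cid] <- (if (cid %in% names(upper)) upper[[cid]] else 0) + max(hi, 0)
    if (lo > 0 || hi < 0) {
      stop("canonicalize_model: exchange ", rid, " forces nonzero net flux; ",
           "cannot express as environment bounds")
    }
    drop[j] <- TRUE
  }
  if (!any(drop)) {
    out <- raw
    out$default_env <- growth_env(lower = lower, upper = upper)
    return(out)
  }
  keep <- !drop
  metabolic_model(raw$model_id, S[, keep, drop = FALSE],
                  lb = raw$lb[keep], ub = raw$ub[keep],
                  compartment = unname(raw$compartment),
                  biomass_id = raw$biomass_id,
                  default_env = growth_env(lower = lower, upper = upper),
                  compound_names = unname(raw$compound_names))
}

.COMPARTMENT_CODE <- c(extracellular = "e", cytoplasm = "c", periplasm = "p")

#' Write a metabolic model as SBML (Level 3 + fbc v2)
#'
#' The default environment is materialized as exchange reactions
#' (`EX_<compound>`, compound as sole reactant) whose flux bounds carry
#' the environment bounds, so `read_sbml_model()` followed by
#' [canonicalize_model()] recovers the model exactly.
#'
#' @param model a canonicalized [metabolic_model()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            .SBML_NS, .FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$model_id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(.COMPARTMENT_CODE[model$compartment])),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$S))) {
    cid <- rownames(model$S)[i]
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(cid), esc(model$compound_names[[cid]]),
      .COMPARTMENT_CODE[[model$compartment[[cid]]]]))
  }
  lines <- c(lines, '    </listOfSpecies>')

  # flux-bound parameters: model reactions then exchanges for the default env
  env_ids <- sort(union(names(model$default_env$lower),
                        names(model$default_env$upper)))
  all_lb <- c(model$lb, stats::setNames(env_lower_for(model$default_env, env_ids),
                                        paste0("EX_", env_ids)))
  all_ub <- c(model$ub, stats::setNames(env_upper_for(model$default_env, env_ids),
                                        paste0("EX_", env_ids)))
  lines <- c(lines, '    <listOfParameters>')
  for (k in seq_along(all_lb)) {
    lines <- c(lines,
               sprintf('      <parameter id="bnd_lo_%d" value="%s" constant="true"/>', k, num(all_lb[[k]])),
               sprintf('      <parameter id="bnd_hi_%d" value="%s" constant="true"/>', k, num(all_ub[[k]])))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')

  write_rxn <- function(rid, st, k) {
    out <- sprintf('      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="bnd_lo_%d" fbc:upperFluxBound="bnd_hi_%d">',
                   esc(rid), if (all_lb[[k]] < 0) "true" else "false", k, k)
    for (side in c(-1, 1)) {
      part <- st[sign(st) == side]
      if (length(part)) {
        tag <- if (side < 0) "listOfReactants" else "listOfProducts"
        out <- c(out, sprintf('        <%s>', tag),
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(part)), num(abs(part))),
                 sprintf('        </%s>', tag))
      }
    }
    c(out, '      </reaction>')
  }
  for (k in seq_len(ncol(model$S))) {
    st <- model$S[, k]
    st <- st[st != 0]
    lines <- c(lines, write_rxn(colnames(model$S)[k], st, k))
  }
  for (i in seq_along(env_ids)) {
    st <- stats::setNames(-1, env_ids[i])
    lines <- c(lines, write_rxn(paste0("EX_", env_ids[i]), st, ncol(model$S) + i))
  }
  lines <- c(lines,
             '    </listOfReactions>',
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>',
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     esc(model$biomass_id)),
             '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>',
             '  </model>',
             '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic fixture's models as SBML
#'
#' @param spec a [make_fixture()] / [random_toy_pair()] result.
#' @param dir existing output directory.
#' @return Character vector of file paths.
#' @export
write_fixture_sbml <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_pair_spec"))
  if (!dir.exists(dir)) stop("write_fixture_sbml: directory '", dir,
                             "' does not exist")
  vapply(spec$models, function(m) {
    write_sbml_model(m, file.path(dir, paste0(m$model_id, ".xml")))
  }, character(1))
}

#' Write / read the canonical model JSON
#'
#' A stable plain-text serialization of a canonicalized model: reactions as
#' sparse stoichiometry maps with sorted keys, bounds, compartments, and
#' the default environment.
#'
#' @param model a [metabolic_model()].
#' @param path file path.
#' @return `write_model_json`: the path, invisibly. `read_model_json`: a
#'   [metabolic_model()].
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_len(ncol(model$S)), function(j) {
    st <- model$S[, j]; st <- st[st != 0]
    st <- st[order(names(st))]
    list(stoich = as.list(st), lb = model$lb[[j]], ub = model$ub[[j]])
  })
  names(rxns) <- colnames(model$S)
  obj <- list(
    model_id = model$model_id,
    biomass_id = model$biomass_id,
    compounds = data.frame(id = rownames(model$S),
                           name = unname(model$compound_names),
                           compartment = unname(model$compartment),
                           stringsAsFactors = FALSE),
    reactions = rxns,
    default_env = list(
      lower = as.list(model$default_env$lower[order(names(model$default_env$lower))]),
      upper = as.list(model$default_env$upper[order(names(model$default_env$upper))])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rxns <- lapply(obj$reactions, function(r) {
    list(stoich = unlist(r$stoich), lb = r$lb, ub = r$ub)
  })
  compounds <- do.call(rbind, lapply(obj$compounds, function(cc) {
    data.frame(id = cc$id, name = cc$name, compartment = cc$compartment,
               stringsAsFactors = FALSE)
  }))
  model_from_reactions(
    obj$model_id, compounds, rxns, obj$biomass_id,
    default_env = growth_env(lower = unlist(obj$default_env$lower),
                             upper = unlist(obj$default_env$upper)))
}

#' Write / read an environment as TSV
#'
#' Columns `compound_id`, `lower_bound`, `upper_bound`; full-precision
#' decimal text so a write/read round trip is exact.
#'
#' @param env a [growth_env()].
#' @param path file path.
#' @return `write_environment`: the path, invisibly. `read_environment`: a
#'   [growth_env()].
#' @export
write_environment <- function(env, path) {
  ids <- sort(union(names(env$lower), names(env$upper)))
  lines <- c("compound_id\tlower_bound\tupper_bound",
             sprintf("%s\t%.17g\t%.17g", ids,
                     env_lower_for(env, ids), env_upper_for(env, ids)))
  if (length(ids) == 0) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]],
                                       c("compound_id", "lower_bound", "upper_bound"))) {
    stop("read_environment: missing or malformed header in ", path)
  }
  lower <- numeric(); upper <- numeric()
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(trimws(lines[i]))) next
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) != 3) {
      stop("read_environment: malformed row at line ", i, " of ", path)
    }
    lo <- suppressWarnings(as.numeric(parts[2]))
    hi <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(lo) || is.na(hi)) {
      stop("read_environment: non-numeric bound at line ", i, " of ", path)
    }
    if (lo > 0) stop("read_environment: positive lower bound for '",
                     parts[1], "' at line ", i)
    if (hi < 0) stop("read_environment: negative upper bound for '",
                     parts[1], "' at line ", i)
    lower[parts[1]] <- lo
    upper[parts[1]] <- hi
  }
  growth_env(lower = lower, upper = upper)
}
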