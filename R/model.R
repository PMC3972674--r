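# Rule language: molecule types with named sites and modification states,
# BNGL-style patterns, and implicit reaction rules applied as graph rewrites.

.trim <- function(x) gsub("^\\s+|\\s+$", "", x)

# split a string at top-level occurrences of a single-character separator,
# ignoring separators inside parentheses
.split_top <- function(s, sep) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  out <- character()
  cur <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L) {
      out <- c(out, paste(cur, collapse = ""))
      cur <- character()
    } else cur <- c(cur, ch)
  }
  c(out, paste(cur, collapse = ""))
}

.name_rx <- "[A-Za-z_][A-Za-z0-9_]*"

#' Declare an elementary molecule type
#'
#' An elementary molecule is the basic simulated building block: a named
#' entity carrying an ordered list of sites. Duplicate site names are
#' permitted (generic sites) and are interchangeable for pattern matching.
#' Each site may carry a list of allowed modification labels; the first
#' label is the default state of newly created particles.
#'
#' @param name type name (unique within a model).
#' @param sites character vector of site names; duplicates allowed.
#' @param mods optional list (same length as `sites`) of allowed
#'   modification labels per site occurrence; `character()` means the site
#'   carries no modification.
#' @return an object of class `srbm_molecule_type`.
#' @export
molecule_type <- function(name, sites = character(), mods = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl(paste0("^", .name_rx, "$"), name))
    stop("invalid molecule type name: ", name)
  sites <- as.character(sites)
  if (is.null(mods)) mods <- rep(list(character()), length(sites))
  if (length(mods) != length(sites))
    stop("mods must have one entry per site")
  structure(list(name = name, sites = sites, mods = mods),
            class = "srbm_molecule_type")
}

# parse one site token of a pattern: name[~mod][!bond] in any order
.parse_site_pattern <- function(tok, where = "") {
  m <- regmatches(tok, regexec(paste0("^(", .name_rx, ")"), tok))[[1]]
  if (length(m) == 0L) stop("bad site token '", tok, "'", where)
  site <- m[2]
  rest <- substr(tok, nchar(site) + 1L, nchar(tok))
  bond <- "free"   # a mentioned site without a bond spec must be unbound
  mod <- NA_character_
  while (nzchar(rest)) {
    if (startsWith(rest, "~")) {
      m <- regmatches(rest, regexec(paste0("^~(", .name_rx, ")"), rest))[[1]]
      if (length(m) == 0L) stop("bad modification in '", tok, "'", where)
      mod <- m[2]
      rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
    } else if (startsWith(rest, "!")) {
      m <- regmatches(rest, regexec("^!([0-9]+|\\+|\\?)", rest))[[1]]
      if (length(m) == 0L) stop("bad bond spec in '", tok, "'", where)
      bond <- switch(m[2], "+" = "any", "?" = "wild", as.integer(m[2]))
      rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
    } else stop("trailing characters in site token '", tok, "'", where)
  }
  list(site = site, bond = bond, mod = mod)
}

# parse one molecule of a pattern: Name or Name(tok,tok,...)
.parse_pattern_mol <- function(s, where = "") {
  s <- .trim(s)
  m <- regmatches(s, regexec(paste0("^(", .name_rx, ")\\((.*)\\)$"), s))[[1]]
  if (length(m) > 0L) {
    type <- m[2]
    inner <- .trim(m[3])
    toks <- if (nzchar(inner)) .trim(.split_top(inner, ",")) else character()
    sites <- lapply(toks, .parse_site_pattern, where = where)
  } else if (grepl(paste0("^", .name_rx, "$"), s)) {
    type <- s
    sites <- list()
  } else stop("bad molecule pattern '", s, "'", where)
  list(type = type, sites = sites)
}

#' Parse a complex pattern
#'
#' A complex pattern is a connected set of molecule patterns joined by
#' numbered bond labels, e.g. `"A(a!1).A(a!1,b~mod)"`. Omitted sites are
#' wildcards; a mentioned site with no bond spec must be unbound; `!+` means
#' bound to anything; `!?` leaves the bond state unspecified.
#'
#' @param s pattern string.
#' @return an object of class `srbm_pattern`.
#' @export
parse_pattern <- function(s) {
  where <- paste0(" in pattern '", s, "'")
  mols <- lapply(.split_top(.trim(s), "."), .parse_pattern_mol, where = where)
  pat <- structure(list(mols = mols), class = "srbm_pattern")
  .validate_pattern(pat, where)
  pat
}

.pattern_bonds <- function(pat) {
  # matrix with one row per labelled bond end: label, mol, occ
  out <- NULL
  for (k in seq_along(pat$mols)) {
    ss <- pat$mols[[k]]$sites
    for (o in seq_along(ss)) {
      b <- ss[[o]]$bond
      if (is.numeric(b)) out <- rbind(out, c(b, k, o))
    }
  }
  out
}

.validate_pattern <- function(pat, where = "") {
  ends <- .pattern_bonds(pat)
  if (!is.null(ends)) {
    tab <- table(ends[, 1])
    bad <- names(tab)[tab != 2L]
    if (length(bad))
      stop("bond label(s) ", paste(bad, collapse = ", "),
           " must appear exactly twice", where)
  }
  # connectivity over molecules via shared bond labels
  nm <- length(pat$mols)
  if (nm > 1L) {
    parent <- seq_len(nm)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (!is.null(ends)) for (lab in unique(ends[, 1])) {
      ms <- ends[ends[, 1] == lab, 2]
      a <- find(ms[1]); b <- find(ms[2])
      parent[a] <- b
    }
    if (length(unique(vapply(seq_len(nm), find, 1L))) > 1L)
      stop("complex pattern is not connected", where)
  }
  invisible(pat)
}

# align lhs and rhs of a rule, derive its actions and kind
.finalize_rule <- function(id, lhs, rhs, rate, switch_tag = NA_character_) {
  flat_l <- do.call(c, lapply(lhs, `[[`, "mols"))
  flat_r <- do.call(c, lapply(rhs, `[[`, "mols"))
  tl <- vapply(flat_l, `[[`, "", "type")
  tr <- vapply(flat_r, `[[`, "", "type")
  if (length(tl) != length(tr) || any(tl != tr))
    stop("rule '", id, "': molecules are not conserved (lhs ",
         paste(tl, collapse = "+"), " vs rhs ", paste(tr, collapse = "+"), ")")
  # per-molecule site alignment by occurrence order within each site name
  mods <- NULL
  bond_of <- function(flat, offs) {
    # set of bonds as "molA.occA-molB.occB" keys plus matrix
    res <- NULL
    lab <- list()
    for (k in seq_along(flat)) {
      ss <- flat[[k]]$sites
      for (o in seq_along(ss)) {
        b <- ss[[o]]$bond
        if (is.numeric(b)) lab[[as.character(b)]] <-
            rbind(lab[[as.character(b)]], c(k, o))
      }
    }
    for (l in lab) {
      if (nrow(l) != 2L) stop("rule '", id, "': dangling bond label")
      res <- rbind(res, c(l[1, ], l[2, ]))
    }
    res
  }
  for (k in seq_along(flat_l)) {
    sl <- flat_l[[k]]$sites
    sr <- flat_r[[k]]$sites
    nml <- vapply(sl, `[[`, "", "site")
    nmr <- vapply(sr, `[[`, "", "site")
    if (length(nml) != length(nmr) || !identical(sort(nml), sort(nmr)))
      stop("rule '", id, "': molecule ", k,
           " mentions different sites on the two sides")
    # reorder rhs site mentions to lhs occurrence order per name
    ord <- integer(length(nml))
    used <- logical(length(nmr))
    for (o in seq_along(nml)) {
      j <- which(nmr == nml[o] & !used)[1]
      used[j] <- TRUE
      ord[o] <- j
    }
    flat_r[[k]]$sites <- sr[ord]
    for (o in seq_along(nml)) {
      ml <- sl[[o]]$mod
      mr <- flat_r[[k]]$sites[[o]]$mod
      if (!is.na(mr) && (is.na(ml) || ml != mr))
        mods <- rbind(mods, data.frame(mol = k, occ = o, mod = mr,
                                       stringsAsFactors = FALSE))
    }
  }
  bl <- bond_of(flat_l)
  br <- bond_of(flat_r)
  key <- function(m) if (is.null(m)) character() else
    apply(m, 1, function(r) paste(r, collapse = "."))
  formed <- if (is.null(br)) NULL else br[!(key(br) %in% key(bl)), , drop = FALSE]
  broken <- if (is.null(bl)) NULL else bl[!(key(bl) %in% key(br)), , drop = FALSE]
  nf <- if (is.null(formed)) 0L else nrow(formed)
  nb <- if (is.null(broken)) 0L else nrow(broken)
  if (nf + nb > 1L)
    stop("rule '", id, "': at most one bond may change")
  if (nf + nb == 0L && is.null(mods))
    stop("rule '", id, "': no structural difference between lhs and rhs")
  kind <- if (nf == 1L) "bind" else if (nb == 1L) "unbind" else
    if (length(flat_l) > 1L) "modify-propagate" else "modify"
  structure(list(id = id, lhs = lhs, rhs = rhs, rate = rate,
                 switch = switch_tag, kind = kind,
                 flat_lhs = flat_l, flat_rhs = flat_r,
                 actions = list(form = formed, broken = broken, mods = mods)),
            class = "srbm_rule")
}

#' Parse a model description
#'
#' Reads the BNGL-subset dialect documented in `inst/grammar/bngl-subset.md`:
#' a `molecule types` block declaring elementary molecules with their sites
#' and modification labels, an optional `parameters` block of named numeric
#' values, and a `reaction rules` block. Rules are unidirectional
#' (`lhs -> rhs rate [@switch]`); bimolecular rates are per-encounter binding
#' probabilities, unimolecular rates first-order constants per unit time.
#'
#' @param text model source, as a single string or character vector of lines.
#' @return an object of class `srbm_model` with fields `types`, `rules`,
#'   `params` and `switches`.
#' @examples
#' m <- parse_model("
#' begin molecule types
#' A(a,a)
#' end molecule types
#' begin reaction rules
#' dimerize: A(a) + A(a) -> A(a!1).A(a!1) 1.0
#' end reaction rules
#' ")
#' m$rules[[1]]$kind  # "bind"
#' @export
parse_model <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", lines)
  types <- list()
  params <- c(numeric())
  rules <- list()
  block <- NA_character_
  for (i in seq_along(lines)) {
    ln <- .trim(lines[i])
    if (!nzchar(ln)) next
    err <- function(...) stop("line ", i, ": ", ..., call. = FALSE)
    if (grepl("^begin\\s+", ln)) {
      b <- .trim(sub("^begin\\s+", "", ln))
      if (!b %in% c("molecule types", "parameters", "reaction rules"))
        err("unknown block '", b, "'")
      if (!is.na(block)) err("nested block")
      block <- b
      next
    }
    if (grepl("^end\\s+", ln)) {
      b <- .trim(sub("^end\\s+", "", ln))
      if (is.na(block) || b != block) err("unmatched 'end ", b, "'")
      block <- NA_character_
      next
    }
    if (is.na(block)) err("text outside of a block: '", ln, "'")
    if (block == "parameters") {
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) != 2L || is.na(suppressWarnings(as.numeric(toks[2]))))
        err("expected 'name value'")
      params[toks[1]] <- as.numeric(toks[2])
    } else if (block == "molecule types") {
      m <- regmatches(ln, regexec(paste0("^(", .name_rx, ")\\((.*)\\)$"), ln))[[1]]
      if (length(m) == 0L) {
        if (!grepl(paste0("^", .name_rx, "$"), ln)) err("bad type declaration")
        m <- c(ln, ln, "")
      }
      nm <- m[2]
      if (nm %in% names(types)) err("duplicate molecule type '", nm, "'")
      inner <- .trim(m[3])
      toks <- if (nzchar(inner)) .trim(.split_top(inner, ",")) else character()
      sites <- character()
      mods <- list()
      for (tok in toks) {
        parts <- strsplit(tok, "~", fixed = TRUE)[[1]]
        if (!grepl(paste0("^", .name_rx, "$"), parts[1]))
          err("bad site name '", parts[1], "'")
        sites <- c(sites, parts[1])
        mods <- c(mods, list(if (length(parts) > 1L) parts[-1] else character()))
      }
      types[[nm]] <- molecule_type(nm, sites, mods)
    } else { # reaction rules
      id <- sprintf("r%d", length(rules) + 1L)
      m <- regmatches(ln, regexec(paste0("^(", .name_rx, ")\\s*:\\s*(.*)$"), ln))[[1]]
      body <- ln
      if (length(m) > 0L) { id <- m[2]; body <- m[3] }
      if (grepl("<->", body, fixed = TRUE))
        err("reversible rules are not supported; write two rules")
      halves <- strsplit(body, "->", fixed = TRUE)[[1]]
      if (length(halves) != 2L) err("rule must contain exactly one '->'")
      lhs_s <- .trim(halves[1])
      rhs_toks <- strsplit(.trim(halves[2]), "\\s+")[[1]]
      switch_tag <- NA_character_
      if (length(rhs_toks) && grepl("^@", rhs_toks[length(rhs_toks)])) {
        switch_tag <- sub("^@", "", rhs_toks[length(rhs_toks)])
        rhs_toks <- rhs_toks[-length(rhs_toks)]
      }
      if (length(rhs_toks) < 2L) err("rule is missing a rate")
      rate_tok <- rhs_toks[length(rhs_toks)]
      rhs_s <- paste(rhs_toks[-length(rhs_toks)], collapse = " ")
      rate <- suppressWarnings(as.numeric(rate_tok))
      if (is.na(rate)) {
        if (!rate_tok %in% names(params))
          err("unknown rate parameter '", rate_tok, "'")
        rate <- params[[rate_tok]]
      }
      lhs <- lapply(.trim(.split_top(lhs_s, "+")), parse_pattern)
      rhs <- lapply(.trim(.split_top(rhs_s, "+")), parse_pattern)
      rl <- tryCatch(.finalize_rule(id, lhs, rhs, rate, switch_tag),
                     error = function(e) err(conditionMessage(e)))
      rules[[length(rules) + 1L]] <- rl
    }
  }
  if (!is.na(block)) stop("unterminated block '", block, "'")
  mdl <- structure(list(types = types, rules = rules, params = params,
                        switches = .default_switches(rules)),
                   class = "srbm_model")
  .validate_model(mdl)
  mdl
}

.default_switches <- function(rules) {
  tags <- unique(stats::na.omit(vapply(rules, `[[`, "", "switch")))
  setNames(rep(TRUE, length(tags)), tags)
}

.validate_model <- function(model) {
  for (r in model$rules) {
    for (pm in c(r$flat_lhs, r$flat_rhs)) {
      ty <- model$types[[pm$type]]
      if (is.null(ty))
        stop("rule '", r$id, "': unknown molecule type '", pm$type, "'")
      for (sp in pm$sites) {
        occ <- which(ty$sites == sp$site)
        if (length(occ) == 0L)
          stop("rule '", r$id, "': molecule '", pm$type,
               "' has no site '", sp$site, "'")
        if (!is.na(sp$mod) &&
            !any(vapply(occ, function(o) sp$mod %in% ty$mods[[o]], TRUE)))
          stop("rule '", r$id, "': site '", sp$site, "' of '", pm$type,
               "' has no modification state '", sp$mod, "'")
      }
    }
  }
  invisible(model)
}

#' @export
print.srbm_model <- function(x, ...) {
  cat("srbm model:", length(x$types), "molecule types,",
      length(x$rules), "rules\n")
  for (ty in x$types) {
    ss <- mapply(function(s, m) {
      if (length(m)) paste0(s, paste0("~", m, collapse = "")) else s
    }, ty$sites, ty$mods)
    cat("  ", ty$name, "(", paste(ss, collapse = ","), ")\n", sep = "")
  }
  for (r in x$rules)
    cat("  ", r$id, " [", r$kind, "] rate=", r$rate,
        if (!is.na(r$switch)) paste0(" @", r$switch) else "", "\n", sep = "")
  invisible(x)
}

#' Read a tab-separated interaction table
#'
#' Each row of the table (columns `protein_a`, `protein_b`, `site_a`,
#' `site_b`, and optionally `rate_tag` and `switch_tag`) expands into one
#' bind rule `A(sa) + B(sb) -> A(sa!1).B(sb!1)`.
#'
#' @param file path to a TSV file, or a data frame with those columns.
#' @return the interaction table as a data frame.
#' @seealso [interactions_to_rules()]
#' @export
read_interaction_table <- function(file) {
  df <- if (is.data.frame(file)) file else
    read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("protein_a", "protein_b", "site_a", "site_b")
  if (!all(need %in% names(df)))
    stop("interaction table needs columns ", paste(need, collapse = ", "))
  df
}

#' Expand an interaction table into bind rules
#'
#' @param df interaction table (see [read_interaction_table()]).
#' @param params named numeric vector resolving `rate_tag` entries; rows
#'   without a tag (or with a tag absent from `params`) get `default_rate`.
#' @param default_rate binding probability per encounter used when no rate
#'   tag resolves.
#' @return list of `srbm_rule` objects.
#' @export
interactions_to_rules <- function(df, params = numeric(), default_rate = 1) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    rate <- default_rate
    if (!is.null(r$rate_tag) && !is.na(r$rate_tag) && nzchar(r$rate_tag) &&
        r$rate_tag %in% names(params))
      rate <- params[[r$rate_tag]]
    sw <- NA_character_
    if (!is.null(r$switch_tag) && !is.na(r$switch_tag) && nzchar(r$switch_tag))
      sw <- r$switch_tag
    lhs <- list(parse_pattern(sprintf("%s(%s)", r$protein_a, r$site_a)),
                parse_pattern(sprintf("%s(%s)", r$protein_b, r$site_b)))
    rhs <- list(parse_pattern(sprintf("%s(%s!1).%s(%s!1)",
                                      r$protein_a, r$site_a,
                                      r$protein_b, r$site_b)))
    .finalize_rule(sprintf("%s-%s", r$protein_a, r$protein_b),
                   lhs, rhs, rate, sw)
  })
}
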