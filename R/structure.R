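# Hierarchical protein model: Protein > Chain > Residue > atom table,
# fixed-column PDB reading/writing, and "chain:RESnum" site addressing.

.empty_atoms <- function() {
  data.frame(name = character(0), element = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             occupancy = numeric(0), altloc = character(0),
             hetero = logical(0), stringsAsFactors = FALSE)
}

#' Construct a residue
#'
#' @param name 3-letter residue code.
#' @param number Integer residue sequence number (taken verbatim from input;
#'   never renumbered).
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z` and
#'   optionally `occupancy`, `altloc`, `hetero`.
#' @param insertion_code Optional single-character insertion code.
#' @return A `ptm_residue`.
#' @export
ptm_residue <- function(name, number, atoms = .empty_atoms(), insertion_code = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!nrow(atoms)) atoms <- .empty_atoms() else {
    if (is.null(atoms$occupancy)) atoms$occupancy <- 1
    if (is.null(atoms$altloc)) atoms$altloc <- ""
    if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  }
  if (anyDuplicated(atoms$name)) stop("duplicate atom names within residue ", name, number)
  structure(list(name = toupper(name), number = as.integer(number),
                 insertion_code = insertion_code, atoms = atoms),
            class = "ptm_residue")
}

#' Construct a chain
#' @param id Single-character chain identifier.
#' @param residues List of `ptm_residue` objects in sequence order.
#' @return A `ptm_chain`.
#' @export
ptm_chain <- function(id, residues = list()) {
  keys <- vapply(residues, function(r) paste0(r$number, r$insertion_code), "")
  if (anyDuplicated(keys)) stop("duplicate residue numbers in chain ", id)
  structure(list(id = id, residues = residues), class = "ptm_chain")
}

#' Construct a protein
#' @param chains List of `ptm_chain` objects.
#' @param title Free-text title.
#' @return A `ptm_protein`.
#' @export
ptm_protein <- function(chains = list(), title = "") {
  ids <- vapply(chains, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate chain ids")
  structure(list(title = title, chains = chains), class = "ptm_protein")
}

#' @export
print.ptm_protein <- function(x, ...) {
  nres <- sum(vapply(x$chains, function(ch) length(ch$residues), 0L))
  nat <- nrow(protein_atoms(x))
  cat(sprintf("<ptm_protein> %d chain(s), %d residue(s), %d atom(s)\n",
              length(x$chains), nres, nat))
  invisible(x)
}

#' Flatten a protein to a single atom table
#'
#' @param protein A `ptm_protein`.
#' @return Data frame with columns `chain`, `resname`, `resnum`, `icode`,
#'   `name`, `element`, `x`, `y`, `z`, `occupancy`, `altloc`, `hetero`.
#' @export
protein_atoms <- function(protein) {
  rows <- list()
  for (ch in protein$chains) {
    for (res in ch$residues) {
      if (!nrow(res$atoms)) next
      a <- res$atoms
      a$chain <- ch$id
      a$resname <- res$name
      a$resnum <- res$number
      a$icode <- res$insertion_code
      rows[[length(rows) + 1L]] <- a
    }
  }
  if (!length(rows)) {
    out <- .empty_atoms()
    out$chain <- character(0); out$resname <- character(0)
    out$resnum <- integer(0); out$icode <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("chain", "resname", "resnum", "icode", "name", "element",
          "x", "y", "z", "occupancy", "altloc", "hetero")]
}

# guess the element from a PDB atom name when columns 77-78 are blank
.element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("SE", "CL", "BR", "FE", "ZN", "MG", "NA")) return(two)
  toupper(substr(nm, 1, 1))
}

#' Read a PDB-format structure
#'
#' Parses fixed-column ATOM/HETATM records. Chains and residues are kept in
#' file order; alternate locations are resolved to the highest occupancy
#' (ties broken by file order); HETATM records are retained and flagged
#' `hetero`. Residue numbering is taken verbatim from the file.
#'
#' @param source Path to a PDB file, a connection, or a character vector of
#'   PDB lines.
#' @return A `ptm_protein`.
#' @export
read_pdb <- function(source) {
  if (is.character(source) && length(source) == 1 && !grepl("\n", source) &&
      file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  recs <- grep("^(ATOM  |HETATM)", lines)
  if (!length(recs)) stop("no ATOM/HETATM records: empty structure")
  title <- sub("^TITLE\\s+", "", grep("^TITLE", lines, value = TRUE)[1])
  if (is.na(title)) title <- ""

  f <- function(ln, from, to) substr(ln, from, to)
  parse_num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      bad <- lineno[is.na(v)][1]
      stop(sprintf("malformed PDB record (bad %s) at line %d: %s",
                   what, bad, lines[bad]))
    }
    v
  }
  ln <- lines[recs]
  if (any(nchar(ln) < 54)) {
    bad <- recs[nchar(ln) < 54][1]
    stop(sprintf("malformed PDB record (too short) at line %d: %s", bad, lines[bad]))
  }
  df <- data.frame(
    hetero = substr(ln, 1, 6) == "HETATM",
    name = trimws(f(ln, 13, 16)),
    altloc = trimws(f(ln, 17, 17)),
    resname = trimws(f(ln, 18, 20)),
    chain = f(ln, 22, 22),
    icode = trimws(f(ln, 27, 27)),
    stringsAsFactors = FALSE
  )
  df$resnum <- as.integer(parse_num(f(ln, 23, 26), "residue number", recs))
  df$x <- parse_num(f(ln, 31, 38), "x coordinate", recs)
  df$y <- parse_num(f(ln, 39, 46), "y coordinate", recs)
  df$z <- parse_num(f(ln, 47, 54), "z coordinate", recs)
  occ <- trimws(f(ln, 55, 60))
  df$occupancy <- ifelse(occ == "", 1, suppressWarnings(as.numeric(occ)))
  df$occupancy[is.na(df$occupancy)] <- 1
  df$element <- trimws(toupper(f(ln, 77, 78)))
  blank <- df$element == ""
  if (any(blank)) df$element[blank] <- vapply(df$name[blank], .element_from_name, "")

  # altloc resolution: within (chain, resnum, icode, atom name) keep the
  # highest occupancy; ties broken by file order (stable order of `order`)
  key <- paste(df$chain, df$resnum, df$icode, df$name, sep = "\r")
  keep <- rep(TRUE, nrow(df))
  dupgrp <- key %in% key[duplicated(key)]
  if (any(dupgrp)) {
    for (k in unique(key[dupgrp])) {
      idx <- which(key == k)
      best <- idx[order(-df$occupancy[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]

  chains <- list()
  for (cid in unique(df$chain)) {
    sub <- df[df$chain == cid, , drop = FALSE]
    reskey <- paste(sub$resnum, sub$icode, sep = "\r")
    residues <- lapply(unique(reskey), function(k) {
      rs <- sub[reskey == k, , drop = FALSE]
      ptm_residue(rs$resname[1], rs$resnum[1],
                  atoms = data.frame(name = rs$name, element = rs$element,
                                     x = rs$x, y = rs$y, z = rs$z,
                                     occupancy = rs$occupancy, altloc = rs$altloc,
                                     hetero = rs$hetero, stringsAsFactors = FALSE),
                  insertion_code = rs$icode[1])
    })
    chains[[length(chains) + 1L]] <- ptm_chain(cid, residues)
  }
  ptm_protein(chains, title = title)
}

#' Write a protein in PDB format
#'
#' Emits fixed-column ATOM/HETATM records with coordinates to three decimals,
#' a TER record after each chain, and a final END. Writing the result of
#' [read_pdb()] again is byte-stable.
#'
#' @param protein A non-empty `ptm_protein`.
#' @param path Optional file path; when `NULL` the text is returned
#'   invisibly as a character scalar.
#' @return The PDB text, invisibly when written to `path`.
#' @export
write_pdb <- function(protein, path = NULL) {
  at <- protein_atoms(protein)
  if (!nrow(at)) stop("cannot write an empty protein")
  if (any(nchar(at$name) > 4)) {
    stop("atom name longer than 4 characters: ",
         paste(unique(at$name[nchar(at$name) > 4]), collapse = ", "))
  }
  lines <- character(0)
  if (nzchar(protein$title)) lines <- sprintf("TITLE     %s", protein$title)
  serial <- 0L
  for (ch in protein$chains) {
    last <- NULL
    for (res in ch$residues) {
      a <- res$atoms
      for (k in seq_len(nrow(a))) {
        serial <- serial + 1L
        nm <- a$name[k]
        # column-13 convention: 1-letter elements start in column 14
        nm_fmt <- if (nchar(nm) < 4 && nchar(a$element[k]) == 1) paste0(" ", nm) else nm
        lines <- c(lines, sprintf(
          "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (isTRUE(a$hetero[k])) "HETATM" else "ATOM", serial, nm_fmt,
          substr(a$altloc[k], 1, 1), res$name, ch$id, res$number,
          substr(res$insertion_code, 1, 1), a$x[k], a$y[k], a$z[k],
          a$occupancy[k], 0, a$element[k]))
      }
      last <- res
    }
    if (!is.null(last)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d", serial, last$name,
                                ch$id, last$number))
    }
  }
  lines <- c(lines, "END")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Parse a site string
#'
#' Site strings address a residue as chain, colon, optional 3-letter residue
#' name, and residue number: `"A:CYS155"` or `"A:155"`.
#'
#' @param spec Character scalar.
#' @return A `site_selector` with fields `chain`, `resname` (NA when
#'   omitted) and `resnum`.
#' @export
parse_site <- function(spec) {
  if (!is.character(spec) || length(spec) != 1 || !nzchar(spec)) {
    stop("site spec must be a non-empty string")
  }
  m <- regexec("^([A-Za-z0-9]):([A-Za-z]{3})?([0-9]+)$", spec)
  g <- regmatches(spec, m)[[1]]
  if (!length(g)) stop("malformed site string '", spec,
                       "': expected chain:RESnum or chain:num (e.g. \"A:CYS155\")")
  resname <- if (nzchar(g[3])) toupper(g[3]) else NA_character_
  resnum <- as.integer(g[4])
  if (resnum <= 0) stop("residue number must be positive in '", spec, "'")
  structure(list(chain = g[2], resname = resname, resnum = resnum),
            class = "site_selector")
}

#' Format a site selector back to its string form
#' @param site A `site_selector`.
#' @return Character scalar, e.g. `"A:CYS155"`.
#' @export
format_site <- function(site) {
  paste0(site$chain, ":", if (is.na(site$resname)) "" else site$resname, site$resnum)
}

#' Find the residue addressed by a site selector
#'
#' @param protein A `ptm_protein`.
#' @param site A `site_selector` or site string.
#' @return The matching `ptm_residue`.
#' @export
find_residue <- function(protein, site) {
  if (is.character(site)) site <- parse_site(site)
  idx <- .residue_index(protein, site)
  protein$chains[[idx[1]]]$residues[[idx[2]]]
}

# locate (chain index, residue index); mismatch error is distinct from not-found
.residue_index <- function(protein, site) {
  ci <- which(vapply(protein$chains, `[[`, "", "id") == site$chain)
  if (!length(ci)) stop("residue not found: no chain '", site$chain, "'")
  ch <- protein$chains[[ci]]
  ri <- which(vapply(ch$residues, `[[`, 0L, "number") == site$resnum)
  if (!length(ri)) {
    stop("residue not found: chain ", site$chain, " has no residue ", site$resnum)
  }
  ri <- ri[1]
  res <- ch$residues[[ri]]
  if (!is.na(site$resname) && res$name != site$resname) {
    stop("site mismatch: residue ", site$resnum, " in chain ", site$chain,
         " is ", res$name, ", not ", site$resname)
  }
  c(ci, ri)
}

# replace a residue in place
.set_residue <- function(protein, site, residue) {
  idx <- .residue_index(protein, site)
  protein$chains[[idx[1]]]$residues[[idx[2]]] <- residue
  protein
}
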