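# Residue template registry: heavy-atom build recipes in internal
# coordinates, parsed from the versioned text files under
# inst/extdata/templates (schema documented at the top of each file's module).

.template_env <- new.env(parent = emptyenv())

# default backbone torsions: extended beta-strand conformation
.beta_phi <- -135
.beta_psi <- 135

#' List residue template codes shipped with the package
#' @return Character vector of 3-letter codes.
#' @export
list_templates <- function() {
  dir <- system.file("extdata", "templates", package = "ptmforge")
  sort(sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$")))
}

#' Retrieve a residue template
#'
#' Templates hold the ordered heavy-atom roster, per-atom NERF build recipes
#' (three reference atoms + bond/angle/torsion), the chi1/chi2 dihedral
#' definitions with their default values, and the default backbone torsions
#' (extended beta strand).
#'
#' @param code 3-letter residue code (standard amino acid, cap, or PTM
#'   residue such as SNC).
#' @return A `residue_template` list.
#' @export
residue_template <- function(code) {
  code <- toupper(code)
  if (!is.null(.template_env[[code]])) return(.template_env[[code]])
  path <- system.file("extdata", "templates", paste0(code, ".txt"),
                      package = "ptmforge")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown residue template '", code, "'; available: ",
         paste(list_templates(), collapse = ", "))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  atoms <- list(); chis <- list()
  for (tk in toks) {
    if (tk[1] == "CODE") next
    if (tk[1] == "ATOM") {
      if (length(tk) == 4 && tk[4] == "-") {
        atoms[[length(atoms) + 1L]] <- list(name = tk[2], element = tk[3],
                                            refs = NULL)
      } else {
        stopifnot(length(tk) == 9)
        atoms[[length(atoms) + 1L]] <- list(
          name = tk[2], element = tk[3], refs = tk[4:6],
          r = as.numeric(tk[7]), theta = as.numeric(tk[8]), phi = tk[9])
      }
    } else if (tk[1] %in% c("CHI1", "CHI2")) {
      chis[[tolower(tk[1])]] <- list(atoms = tk[2:5], default = as.numeric(tk[6]))
    } else stop("unrecognized template line in ", code, ": ", paste(tk, collapse = " "))
  }
  tpl <- structure(list(code = code,
                        atoms = atoms,
                        atom_names = vapply(atoms, `[[`, "", "name"),
                        elements = vapply(atoms, `[[`, "", "element"),
                        chi = chis,
                        default_phi_psi = c(phi = .beta_phi, psi = .beta_psi)),
                   class = "residue_template")
  .template_env[[code]] <- tpl
  tpl
}

# resolve a phi token ("-122.5", "CHI1", "CHI2+120", "PSI-180") to degrees
.resolve_phi <- function(token, chi1, chi2, psi) {
  v <- suppressWarnings(as.numeric(token))
  if (!is.na(v)) return(v)
  m <- regexec("^(CHI1|CHI2|PSI)([+-][0-9.]+)?$", token)
  g <- regmatches(token, m)[[1]]
  if (!length(g)) stop("bad torsion token in template: ", token)
  base <- switch(g[2], CHI1 = chi1, CHI2 = chi2, PSI = psi)
  off <- if (nzchar(g[3])) as.numeric(g[3]) else 0
  base + off
}

# Build the full atom table of a template given seeded backbone positions.
# `seed` is a named list of positions for the recipe-less atoms (N, CA, C for
# amino acids). chi/psi override template defaults.
.build_from_template <- function(tpl, seed, psi = .beta_psi,
                                 chi1 = NULL, chi2 = NULL) {
  if (is.null(chi1) && !is.null(tpl$chi$chi1)) chi1 <- tpl$chi$chi1$default
  if (is.null(chi2) && !is.null(tpl$chi$chi2)) chi2 <- tpl$chi$chi2$default
  pos <- list()
  for (a in tpl$atoms) {
    if (is.null(a$refs)) {
      if (is.null(seed[[a$name]])) stop("no seed position for backbone atom ", a$name)
      pos[[a$name]] <- seed[[a$name]]
    } else {
      ref <- lapply(a$refs, function(nm) {
        if (is.null(pos[[nm]])) stop("template recipe references unplaced atom ", nm)
        pos[[nm]]
      })
      phi <- .resolve_phi(a$phi, chi1, chi2, psi)
      pos[[a$name]] <- nerf_place(ref[[1]], ref[[2]], ref[[3]],
                                  internal_coord(a$r, a$theta, phi))
    }
  }
  xyz <- do.call(rbind, pos[tpl$atom_names])
  data.frame(name = tpl$atom_names, element = tpl$elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, altloc = "", hetero = FALSE,
             stringsAsFactors = FALSE)
}

# canonical backbone seed for a residue built in free space
.canonical_seed <- function() {
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  th <- (180 - 111.2) * pi / 180
  C <- CA + 1.525 * c(cos(th), sin(th), 0)
  list(N = N, CA = CA, C = C)
}

# transitive dependents of an atom within a template's recipe graph
.template_dependents <- function(tpl, root) {
  moving <- character(0)
  repeat {
    grew <- FALSE
    for (a in tpl$atoms) {
      if (is.null(a$refs) || a$name %in% moving || a$name == root) next
      if (any(a$refs %in% c(root, moving))) {
        moving <- c(moving, a$name)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  moving
}

# atoms moved by a chi rotation: dependents of the chi axis' distal atom,
# plus that atom's recipe siblings placed off the same chi token
.chi_moving_set <- function(tpl, which_chi) {
  chi <- tpl$chi[[which_chi]]
  if (is.null(chi)) return(NULL)
  distal <- chi$atoms[3]          # axis = atoms 2-3 of the chi quadruple
  tip <- chi$atoms[4]
  dep <- .template_dependents(tpl, tip)
  token <- toupper(which_chi)
  siblings <- vapply(tpl$atoms, function(a) {
    !is.null(a$refs) && grepl(paste0("^", token), a$phi)
  }, TRUE)
  unique(c(tip, vapply(tpl$atoms, `[[`, "", "name")[siblings], dep,
           unlist(lapply(vapply(tpl$atoms, `[[`, "", "name")[siblings],
                         function(nm) .template_dependents(tpl, nm)))))
}
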