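#' Define a liposome species
#'
#' A species is one component of a liposome mixture: a truncated-normal
#' diameter distribution (mean and coefficient of variation), a particle
#' concentration, and a membrane label density. Membrane-labeled liposomes
#' carry fluorophores in the bilayer, so per-particle brightness is
#' proportional to surface area (see [brightness_of()]).
#'
#' @param mean_diameter Mean diameter in nm (> 0). Typical extruded sizes are
#'   50, 100, 200 and 400 nm.
#' @param cv Coefficient of variation of the diameter distribution
#'   (sd/mean, >= 0). Extrusion yields roughly 0.25-0.5.
#' @param concentration Particle concentration in pM (>= 0).
#' @param label_density Fluorophores per nm^2 of membrane, arbitrary units;
#'   fixed per experiment.
#' @return An object of class `liposome_species`.
#' @examples
#' liposome_species(200, cv = 0.35, concentration = 100)
#' @export
liposome_species <- function(mean_diameter, cv = 0.35, concentration = 100,
                             label_density = 1) {
  stopifnot(is.numeric(mean_diameter), mean_diameter > 0,
            is.numeric(cv), cv >= 0,
            is.numeric(concentration), concentration >= 0,
            is.numeric(label_density), label_density > 0)
  structure(list(mean_diameter = mean_diameter, cv = cv,
                 concentration = concentration,
                 label_density = label_density),
            class = "liposome_species")
}

#' Surface-area brightness of a membrane-labeled liposome
#'
#' For uniformly membrane-labeled vesicles, fluorescence brightness is
#' proportional to membrane surface area: `label_density * pi * diameter^2`.
#' A 200 nm liposome is therefore 4-fold brighter than a 100 nm one and
#' 16-fold brighter than a 50 nm one.
#'
#' @param diameter Diameter(s) in nm (> 0).
#' @param label_density Fluorophores per nm^2 (arbitrary units).
#' @return Brightness in arbitrary units (label_density * pi * d^2).
#' @examples
#' brightness_of(200) / brightness_of(100)  # 4
#' @export
brightness_of <- function(diameter, label_density = 1) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("diameter must be positive and finite")
  label_density * pi * diameter^2
}

#' Sample a liposome population
#'
#' Draws per-particle diameters from a mixture of [liposome_species()],
#' allocating particles to species in proportion to their concentrations,
#' and attaches per-particle brightness via [brightness_of()]. Diameters are
#' truncated-normal (non-positive draws are redrawn).
#'
#' @param species_list A `liposome_species` or a list of them.
#' @param n_particles Number of particles to draw (>= 1).
#' @param seed Integer seed for reproducibility (or NULL).
#' @return A `bas_population`: list with `species` (data.frame summary),
#'   `particles` (data.frame with `diameter`, `brightness`, `species`) and
#'   `particle_conc`, the concentration in pM represented by each sampled
#'   particle (total concentration / n_particles).
#' @examples
#' pop <- sample_population(liposome_species(200, 0.35, 100), 1000, seed = 1)
#' mean(pop$particles$diameter)
#' @export
sample_population <- function(species_list, n_particles, seed = NULL) {
  if (inherits(species_list, "liposome_species"))
    species_list <- list(species_list)
  if (!is.list(species_list) || length(species_list) == 0L)
    stop("species_list must be a non-empty list of liposome_species")
  stopifnot(n_particles >= 1)
  ok <- vapply(species_list, inherits, logical(1), "liposome_species")
  if (!all(ok)) stop("all elements must be liposome_species")
  sp <- species_table(species_list)
  total <- sum(sp$concentration)
  if (total <= 0) stop("total concentration must be positive to sample")
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_particles,
                                         sp$concentration / total))
    d <- numeric(0); b <- numeric(0); s <- integer(0)
    for (i in seq_len(nrow(sp))) {
      if (counts[i] == 0L) next
      di <- rdiameter(counts[i], sp$mean_diameter[i], sp$cv[i])
      d <- c(d, di)
      b <- c(b, brightness_of(di, sp$label_density[i]))
      s <- c(s, rep.int(i, counts[i]))
    }
    new_population(sp, data.frame(diameter = d, brightness = b, species = s),
                   particle_conc = total / n_particles)
  })
}

species_table <- function(species_list) {
  data.frame(
    mean_diameter = vapply(species_list, `[[`, numeric(1), "mean_diameter"),
    cv            = vapply(species_list, `[[`, numeric(1), "cv"),
    concentration = vapply(species_list, `[[`, numeric(1), "concentration"),
    label_density = vapply(species_list, `[[`, numeric(1), "label_density"))
}

new_population <- function(species, particles, particle_conc) {
  structure(list(species = species, particles = particles,
                 particle_conc = particle_conc),
            class = "bas_population")
}

#' Total particle concentration of a population
#'
#' For sampled populations this is `particle_conc * nrow(particles)` (so it
#' tracks fission, which multiplies particle number); otherwise the sum of
#' the species concentrations.
#'
#' @param pop A `bas_population`.
#' @return Concentration in pM.
#' @export
total_concentration <- function(pop) {
  stopifnot(inherits(pop, "bas_population"))
  if (!is.null(pop$particles)) pop$particle_conc * nrow(pop$particles)
  else sum(pop$species$concentration)
}

#' @export
print.bas_population <- function(x, ...) {
  cat("<bas_population>", format(total_concentration(x), digits = 4), "pM")
  if (!is.null(x$particles))
    cat(";", nrow(x$particles), "sampled particles, mean diameter",
        format(mean(x$particles$diameter), digits = 4), "nm")
  cat("\n")
  invisible(x)
}
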