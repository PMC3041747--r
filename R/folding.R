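# Simplified nearest-neighbor folding model.
#
# The model scores pseudoknot-free secondary structures as a sum of
# nearest-neighbor stacking free energies plus size-dependent loop
# penalties and an affine multiloop term. Stacks carry an enthalpy/entropy
# split so stack free energy at temperature T (Kelvin) is dH - T * dS;
# loop penalties are treated as purely entropic and scale with
# T / 310.15. Magnitudes follow the Turner-style nearest-neighbor
# literature but exact RNAfold/Turner parity is intentionally not a goal:
# the analyses here depend on relative stability across GC composition.

# pair-type order used everywhere: AU, UA, CG, GC, GU, UG
PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

# stack dG at 37 degC, rows = outer pair (i,j), cols = inner pair (i+1,j-1)
.stack_dg37 <- matrix(c(
  # inner:  AU    UA    CG    GC    GU    UG
  -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # outer AU
  -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # outer UA
  -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # outer CG
  -2.2, -2.4, -3.4, -3.3, -1.5, -2.5,  # outer GC
  -1.4, -1.3, -2.5, -2.1, -0.5, -0.4,  # outer GU
  -1.0, -0.6, -1.5, -1.4, -0.2, -0.5   # outer UG
), nrow = 6, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES))

T37_K <- 310.15
RT_LN_COEF <- 1.75 * 0.0019872  # Jacobson-Stockmayer prefactor (kcal/mol/K)

# tabulated small-size loop penalties at 37 degC; larger sizes are
# extrapolated logarithmically
.hairpin37 <- c(3, 5.4, 4, 5.6, 5, 5.7, 6, 5.8, 7, 6.0, 8, 6.1, 9, 6.3)
.bulge37 <- c(1, 3.8, 2, 2.8, 3, 3.2, 4, 3.6, 5, 4.0, 6, 4.4)
.internal37 <- c(2, 1.5, 3, 1.6, 4, 1.7, 5, 2.0, 6, 2.1, 7, 2.3, 8, 2.4, 9, 2.5)

.loop_table37 <- function(tab, min_size, max_len) {
  sizes <- matrix(tab, ncol = 2, byrow = TRUE)
  out <- rep(Inf, max_len)
  out[sizes[, 1]] <- sizes[, 2]
  base_n <- max(sizes[, 1])
  base_e <- sizes[nrow(sizes), 2]
  big <- seq_len(max_len)
  big <- big[big > base_n]
  out[big] <- base_e + RT_LN_COEF * T37_K * log(big / base_n)
  if (min_size > 1) out[seq_len(min_size - 1)] <- Inf
  out
}

#' Build a nearest-neighbor energy model at a given temperature
#'
#' Stack free energies are recomputed as `dH - T * dS` (the enthalpy is
#' derived from the 37 degC table through a fixed enthalpy/free-energy
#' relation), and loop penalties, being entropic, scale with
#' `T_kelvin / 310.15`. All derived parameters are rounded to 0.01
#' kcal/mol so that structure energies are sums of exact hundredths.
#'
#' @param temperature_c folding temperature in degrees Celsius, in (0, 100).
#'   37 is the human/mouse default; 25 and 24 are the nematode and fruit-fly
#'   presets.
#' @param max_len largest loop size tabulated (and hence largest foldable
#'   window).
#' @param min_hairpin minimum unpaired bases in a hairpin loop.
#' @param max_interior largest total unpaired size of a bulge/interior loop.
#' @return an object of class `energy_model`.
#' @examples
#' m37 <- make_model(37)
#' m25 <- make_model(25)
#' # cooling stabilizes stacks uniformly
#' all(m25$stack_dg <= m37$stack_dg)
#' @export
make_model <- function(temperature_c = 37, max_len = 450,
                       min_hairpin = 3, max_interior = 30) {
  if (!is.numeric(temperature_c) || length(temperature_c) != 1L ||
      temperature_c <= 0 || temperature_c >= 100) {
    stop("temperature_c must be a single number in (0, 100)")
  }
  t_k <- temperature_c + 273.15
  # dH chosen so stacks have Turner-like enthalpies (-8 .. -15 kcal/mol)
  # and dS < 0, hence cooling makes every stack more stable
  dh <- -6.0 + 2.5 * .stack_dg37
  ds <- (dh - .stack_dg37) / T37_K
  stack_dg <- round(dh - t_k * ds, 2)
  scale <- t_k / T37_K
  hairpin_dg <- round(.loop_table37(.hairpin37, 3, max_len) * scale, 2)
  bulge_dg <- round(.loop_table37(.bulge37, 1, max_len) * scale, 2)
  internal_dg <- round(.loop_table37(.internal37, 2, max_len) * scale, 2)
  model <- list(
    temperature_c = temperature_c,
    t_kelvin = t_k,
    stack_dg = stack_dg,
    hairpin_dg = hairpin_dg,
    bulge_dg = bulge_dg,
    internal_dg = internal_dg,
    ml_a = round(3.4 * scale, 2),
    ml_b = round(0.4 * scale, 2),
    ml_c = round(0.1 * scale, 2),
    min_hairpin = as.integer(min_hairpin),
    max_interior = as.integer(max_interior),
    max_len = as.integer(max_len)
  )
  class(model) <- "energy_model"
  model
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model>", x$temperature_c, "degC;",
      "stack dG range", min(x$stack_dg), "..", max(x$stack_dg),
      "kcal/mol; multiloop (a,b,c) =",
      paste(c(x$ml_a, x$ml_b, x$ml_c), collapse = ", "), "\n")
  invisible(x)
}

# pair type index (1..6) or 0 for unpairable, on base codes
pair_type_r <- function(a, b) {
  key <- paste0(c("A", "C", "G", "U", "N")[a + 1L],
                c("A", "C", "G", "U", "N")[b + 1L])
  m <- match(key, PAIR_TYPES)
  ifelse(is.na(m), 0L, m)
}

#' Fold a sequence to its minimum free energy structure
#'
#' Dynamic programming (O(n^3), interior loops capped) over pseudoknot-free
#' structures under the given [make_model()] energy model. The open chain
#' scores zero, so the returned MFE is always `<= 0`. Traceback ties are
#' broken deterministically (earliest opening index first).
#'
#' @param sequence nucleotide sequence (`A,C,G,T/U,N`; N never pairs).
#' @param model an `energy_model` from [make_model()].
#' @return a list of class `fold_result`: `mfe` (kcal/mol), `structure`
#'   (dot-bracket), `temperature_c`.
#' @examples
#' fold_mfe("GGGGAAAACCCC", make_model(37))
#' @export
fold_mfe <- function(sequence, model = make_model(37)) {
  stopifnot(inherits(model, "energy_model"))
  codes <- seq_codes(sequence)
  if (length(codes) < 1L) stop("sequence must be non-empty")
  if (length(codes) > model$max_len) {
    stop("sequence longer than model$max_len; rebuild the model")
  }
  res <- .fold_mfe_cpp(codes, model$stack_dg,
                       ifelse(is.finite(model$hairpin_dg), model$hairpin_dg, 1e9),
                       ifelse(is.finite(model$bulge_dg), model$bulge_dg, 1e9),
                       ifelse(is.finite(model$internal_dg), model$internal_dg, 1e9),
                       model$ml_a, model$ml_b, model$ml_c,
                       model$min_hairpin, model$max_interior)
  structure(list(mfe = res$mfe, structure = res$structure,
                 temperature_c = model$temperature_c),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %.2f kcal/mol @ %g degC\n%s\n",
              x$mfe, x$temperature_c, x$structure))
  invisible(x)
}

#' Fold many sequences
#' @param sequences character vector.
#' @param model an `energy_model`.
#' @return numeric vector of MFEs (kcal/mol).
#' @export
fold_mfe_many <- function(sequences, model = make_model(37)) {
  vapply(sequences, function(s) fold_mfe(s, model)$mfe, numeric(1),
         USE.NAMES = FALSE)
}

#' Parse a dot-bracket string into a partner vector
#' @param structure dot-bracket string.
#' @return integer vector; 0 = unpaired, else 1-based partner index.
#' @export
parse_dot_bracket <- function(structure) {
  ch <- seq_chars(structure)
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket characters")
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  partner
}

pairs_to_dot_bracket <- function(pairs, n) {
  db <- rep(".", n)
  if (!is.null(pairs) && length(pairs) > 0) {
    db[pairs[1, ]] <- "("
    db[pairs[2, ]] <- ")"
  }
  paste(db, collapse = "")
}

#' Score a given structure under the energy model (loop decomposition)
#'
#' Independent structure evaluator used as the oracle for the dynamic
#' program: parses the structure into hairpin, stacked-pair, bulge,
#' interior, and multibranch loops and sums their model energies. External
#' bases and branches are free. Structures with illegal pairs, hairpins
#' below the minimum loop size, or interior loops above the model cap score
#' `Inf` (disallowed under the model).
#'
#' @param sequence nucleotide sequence.
#' @param structure dot-bracket string of the same length.
#' @param model an `energy_model`.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure, model = make_model(37)) {
  codes <- seq_codes(sequence)
  partner <- parse_dot_bracket(structure)
  if (length(partner) != length(codes)) stop("structure/sequence length mismatch")
  opens <- which(partner > seq_along(partner))
  total <- 0
  for (i in opens) {
    j <- partner[i]
    if (pair_type_r(codes[i], codes[j]) == 0L) return(Inf)
    # immediate children of pair (i, j)
    children <- matrix(integer(0), nrow = 2)
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children <- cbind(children, c(k, partner[k]))
        k <- partner[k] + 1L
      } else if (partner[k] == 0L) {
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else {
        return(Inf) # crossing / malformed nesting
      }
    }
    nb <- ncol(children)
    if (nb == 0L) {
      size <- j - i - 1L
      if (size < model$min_hairpin) return(Inf)
      total <- total + model$hairpin_dg[size]
    } else if (nb == 1L) {
      k1 <- children[1, 1]; l1 <- children[2, 1]
      s1 <- k1 - i - 1L; s2 <- j - l1 - 1L
      if (s1 + s2 > model$max_interior) return(Inf)
      if (s1 == 0L && s2 == 0L) {
        po <- pair_type_r(codes[i], codes[j])
        pi_ <- pair_type_r(codes[k1], codes[l1])
        total <- total + model$stack_dg[po, pi_]
      } else if (s1 == 0L || s2 == 0L) {
        total <- total + model$bulge_dg[s1 + s2]
      } else {
        total <- total + model$internal_dg[s1 + s2]
      }
    } else {
      total <- total + model$ml_a + model$ml_b * (nb + 1L) +
        model$ml_c * unpaired
    }
    if (!is.finite(total)) return(Inf)
  }
  total
}

# recursively enumerate all pseudoknot-free pair sets over codes[i..j]
.enumerate_pairsets <- function(codes, min_hairpin) {
  n <- length(codes)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L) return(list(NULL))
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1L, j) # i unpaired
    for (k in seq.int(i + min_hairpin + 1L, j)) {
      if (pair_type_r(codes[i], codes[k]) == 0L) next
      inner <- rec(i + 1L, k - 1L)
      after <- if (k + 1L <= j) rec(k + 1L, j) else list(NULL)
      for (a in inner) {
        for (b in after) {
          out[[length(out) + 1L]] <- cbind(c(i, k), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

#' Exhaustively enumerate structures and return the minimum-energy one
#'
#' Brute-force oracle for [fold_mfe()]: enumerates every pseudoknot-free
#' structure with hairpin loops of at least `model$min_hairpin` unpaired
#' bases, scores each with [structure_energy()], and returns the minimum
#' (the open chain, energy 0, is always included).
#'
#' @param sequence nucleotide sequence of length `<= max_len`.
#' @param model an `energy_model`.
#' @param max_len refusal threshold guarding against combinatorial blowup.
#' @return list with `mfe`, `structure` (dot-bracket), `n_structures`.
#' @export
enumerate_structures <- function(sequence, model = make_model(37),
                                 max_len = 18) {
  codes <- seq_codes(sequence)
  n <- length(codes)
  if (n > max_len) stop("sequence longer than max_len = ", max_len)
  sets <- .enumerate_pairsets(codes, model$min_hairpin)
  best_e <- 0
  best_db <- paste(rep(".", n), collapse = "")
  count <- 0L
  for (p in sets) {
    count <- count + 1L
    if (is.null(p) || length(p) == 0L) next
    db <- pairs_to_dot_bracket(p, n)
    e <- structure_energy(sequence, db, model)
    if (e < best_e - 1e-12 ||
        (abs(e - best_e) <= 1e-12 && db < best_db)) {
      best_e <- e
      best_db <- db
    }
  }
  list(mfe = best_e, structure = best_db, n_structures = count)
}

#' Maximum number of nested base pairs (Nussinov bound)
#'
#' @param sequence nucleotide sequence.
#' @param min_loop minimum hairpin loop size.
#' @return integer: maximum number of legal nested pairs.
#' @export
nussinov_max_pairs <- function(sequence, min_loop = 3) {
  .nussinov_cpp(seq_codes(sequence), as.integer(min_loop))
}

#' Validate a fold result's structure string
#'
#' Checks balance, legal pairs (Watson-Crick or GU), and the hairpin
#' minimum-loop constraint.
#' @param sequence nucleotide sequence.
#' @param structure dot-bracket string.
#' @param min_hairpin minimum hairpin loop size.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_structure <- function(sequence, structure, min_hairpin = 3) {
  codes <- seq_codes(sequence)
  partner <- parse_dot_bracket(structure)
  if (length(partner) != length(codes)) stop("length mismatch")
  opens <- which(partner > seq_along(partner))
  for (i in opens) {
    j <- partner[i]
    if (pair_type_r(codes[i], codes[j]) == 0L) {
      stop("illegal pair at ", i, "-", j)
    }
    inside <- if (j - i >= 2L) partner[seq.int(i + 1L, j - 1L)] else integer(0)
    if (all(inside == 0L) && (j - i - 1L) < min_hairpin) {
      stop("hairpin loop below minimum size at ", i, "-", j)
    }
  }
  invisible(TRUE)
}
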