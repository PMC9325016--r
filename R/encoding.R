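# Genotype encoding: pairs (I, Delta) that re-define the flux bounds of
# the control (VM) and bioproduct (Vb) reactions.

#' Define the encoded reaction set and its base bounds
#'
#' The genotype covers the reactions `VM` (control set) followed by `Vb`
#' (bioproducts, leading bioproduct first), two values per reaction, so
#' its length is `2 * (|VM| + |Vb|)`. The two sets must be disjoint and
#' every id must exist in the network. The base bounds recorded here are
#' the network's *original* bounds: decoding always starts from them,
#' never from previously decoded bounds.
#'
#' @param net A `metabolic_network`.
#' @param vm_ids Character vector of control reaction ids (may be empty).
#' @param vb_ids Character vector of bioproduct reaction ids; the first is
#'   the leading bioproduct.
#' @return An `encoding_spec`: list with `vm_ids`, `vb_ids`, `ids`
#'   (concatenated order), `base_lb`, `base_ub` (named numeric) and
#'   `length` (genotype length).
#' @export
encoding_spec <- function(net, vm_ids, vb_ids) {
  stopifnot(inherits(net, "metabolic_network"))
  vm_ids <- as.character(vm_ids)
  vb_ids <- as.character(vb_ids)
  ids <- c(vm_ids, vb_ids)
  if (anyDuplicated(ids))
    stop("VM and Vb must be disjoint and free of duplicates")
  unknown <- setdiff(ids, net$reaction_ids)
  if (length(unknown))
    stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  structure(
    list(vm_ids = vm_ids, vb_ids = vb_ids, ids = ids,
         base_lb = net$lb[ids], base_ub = net$ub[ids],
         length = 2L * length(ids)),
    class = "encoding_spec"
  )
}

#' Decode a genotype into new flux bounds
#'
#' For each encoded reaction `i` with base bounds `(LB_i, UB_i)` and
#' genotype pair `(I_i, Delta_i)` the new bounds are
#' `lb_new = I_i` and `ub_new = (UB_i - I_i) * Delta_i + I_i`.
#' With `I_i` in `[LB_i, UB_i]` and `Delta_i` in `[0, 1]` this always
#' yields `lb_new <= ub_new`. A knockout is the special case
#' `(I, Delta) = (0, 0)`. Reactions outside the encoding keep their
#' original bounds and do not appear in the result.
#'
#' @param w Numeric genotype of length `spec$length`, laid out as
#'   `(I_1, Delta_1, I_2, Delta_2, ...)` in `spec$ids` order (VM block
#'   before Vb block).
#' @param spec An [encoding_spec()].
#' @return Numeric matrix with one row per encoded reaction (rownames =
#'   reaction ids) and columns `lb`, `ub`; directly usable as
#'   `bound_overrides` in [solve_fba()].
#' @examples
#' net <- parse_reaction_table("r : A --> B", default_ub = 10)
#' spec <- encoding_spec(net, character(0), "r")
#' decode_genotype(c(5, 0.5), spec)  # new bounds (5, 7.5)
#' @export
decode_genotype <- function(w, spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (length(w) != spec$length)
    stop("genotype length ", length(w), " != 2(|VM|+|Vb|) = ", spec$length)
  if (!is.numeric(w) || anyNA(w)) stop("genotype must be numeric, no NA")
  I <- w[seq(1L, spec$length, by = 2L)]
  D <- w[seq(2L, spec$length, by = 2L)]
  lb_new <- I
  ub_new <- (spec$base_ub - I) * D + I
  cbind(lb = stats::setNames(lb_new, spec$ids), ub = ub_new)
}

#' Per-variable boxes of the genotype
#'
#' `I_i` ranges over the base bounds `[LB_i, UB_i]`; `Delta_i` over
#' `[0, 1]`. Evolutionary operators clip their output to these boxes.
#'
#' @param spec An [encoding_spec()].
#' @return List with numeric vectors `lower` and `upper` of length
#'   `spec$length`.
#' @export
genotype_bounds <- function(spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  lower <- numeric(spec$length)
  upper <- numeric(spec$length)
  odd <- seq(1L, spec$length, by = 2L)
  lower[odd] <- spec$base_lb
  upper[odd] <- spec$base_ub
  lower[odd + 1L] <- 0
  upper[odd + 1L] <- 1
  list(lower = lower, upper = upper)
}

#' Draw a uniform random genotype
#'
#' Each `I_i` is uniform on its base bounds, each `Delta_i` uniform on
#' `[0, 1]`. Uses R's global RNG stream, so results are reproducible
#' under [set.seed()].
#'
#' @param spec An [encoding_spec()].
#' @return Numeric genotype of length `spec$length`.
#' @export
random_genotype <- function(spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  w <- numeric(spec$length)
  odd <- seq(1L, spec$length, by = 2L)
  w[odd] <- stats::runif(length(odd), spec$base_lb, spec$base_ub)
  w[odd + 1L] <- stats::runif(length(odd))
  w
}

#' Serialise / read a genotype as JSON
#'
#' The JSON object carries the flat value array together with the spec's
#' id lists so a genotype is interpretable on its own.
#'
#' @param w Numeric genotype.
#' @param spec An [encoding_spec()].
#' @param path Output (input) file path.
#' @return `path`, invisibly (`read_genotype_json` returns a list with
#'   `w`, `vm_ids`, `vb_ids`).
#' @export
write_genotype_json <- function(w, spec, path) {
  stopifnot(inherits(spec, "encoding_spec"), length(w) == spec$length)
  jsonlite::write_json(
    list(w = as.numeric(w), vm_ids = spec$vm_ids, vb_ids = spec$vb_ids),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_genotype_json
#' @export
read_genotype_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(w = as.numeric(obj$w), vm_ids = as.character(obj$vm_ids),
       vb_ids = as.character(obj$vb_ids))
}
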