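# The figural analogical reasoning test structure used throughout the
# package's examples, fixtures, and vignette: 27 items built from five
# composition rules (1 principal figure rotation, 2 trapezium rotation,
# 3 entire figure reflection, 4 line subtraction, 5 point movement), with
# rules 1-3 forming a "global" component and rules 4-5 a "local" one.

#' The 27 x 5 figural-analogies Q matrix
#'
#' Binary incidence of the five composition rules in the 27 test items.
#'
#' @return a [feature_matrix()] with items `item1 ... item27` and features
#'   `rule1 ... rule5`.
#' @export
blum_q_matrix <- function() {
  q <- matrix(c(
    # r1 r2 r3 r4 r5
      0, 1, 0, 0, 0,   # 1
      0, 0, 1, 0, 0,   # 2
      1, 0, 0, 0, 0,   # 3
      0, 0, 0, 0, 1,   # 4
      1, 0, 0, 0, 0,   # 5
      0, 1, 0, 0, 0,   # 6
      1, 1, 0, 0, 0,   # 7
      0, 1, 1, 0, 1,   # 8
      1, 1, 0, 1, 1,   # 9
      1, 1, 0, 0, 0,   # 10
      0, 1, 1, 1, 1,   # 11
      1, 0, 0, 0, 1,   # 12
      1, 1, 0, 0, 1,   # 13
      1, 1, 0, 1, 1,   # 14
      0, 1, 0, 0, 1,   # 15
      1, 1, 0, 0, 1,   # 16
      1, 1, 0, 1, 1,   # 17
      1, 1, 0, 0, 0,   # 18
      0, 1, 1, 0, 1,   # 19
      1, 1, 0, 1, 1,   # 20
      0, 1, 1, 0, 0,   # 21
      1, 1, 0, 0, 1,   # 22
      0, 1, 1, 1, 1,   # 23
      0, 0, 1, 0, 1,   # 24
      1, 1, 0, 0, 1,   # 25
      0, 1, 1, 0, 0,   # 26
      1, 1, 0, 0, 1    # 27
  ), nrow = 27, byrow = TRUE)
  validate_feature_matrix(q, item_ids = paste0("item", 1:27),
                          feature_ids = paste0("rule", 1:5))
}

#' The global/local component assignment for the figural-analogies test
#'
#' Rules 1-3 (principal figure rotation, trapezium rotation, reflection) form
#' the global component; rules 4-5 (line subtraction, point movement) form the
#' local component.
#'
#' @return 5 x 2 binary incidence matrix (features x components).
#' @export
blum_component_assignment <- function() {
  inc <- cbind(global = c(1, 1, 1, 0, 0), local = c(0, 0, 0, 1, 1))
  rownames(inc) <- paste0("rule", 1:5)
  inc
}

#' GMLTM-D point estimates for the figural-analogies test
#'
#' The posterior-mean (EAP) parameter values of the GMLTM-D fitted to the
#' original 383-person dataset: rule difficulties per component, group-shared
#' discriminations, and per-item guessing. These serve as the canonical "true"
#' parameter set of the study-emulating simulator fixture.
#'
#' @param q a [feature_matrix()]; defaults to [blum_q_matrix()].
#' @param cs component structure; defaults to the global/local assignment.
#' @return a [parameter_set()] (without abilities).
#' @export
blum_gmltmd_parameters <- function(q = blum_q_matrix(),
                                   cs = derive_component_matrix(q, blum_component_assignment())) {
  eta <- matrix(NA_real_, 5, 2,
                dimnames = list(paste0("rule", 1:5), cs$component_ids))
  eta[1:3, 1] <- c(0.29, 0.77, 0.39)
  eta[4:5, 2] <- c(0.87, -0.79)
  part <- discrimination_partition(q, cs)
  # discrimination per feature-pattern group (global: patterns over rules 1-3;
  # local: patterns over rules 4-5)
  pattern_alpha <- c(
    "001" = 2.42,   # rule 3 alone
    "010" = 1.42,   # rule 2 alone
    "011" = 1.66,   # rules 2+3
    "100" = 1.65,   # rule 1 alone
    "110" = 2.19,   # rules 1+2
    "01"  = 2.66,   # rule 5 alone
    "11"  = 1.78    # rules 4+5
  )
  alpha <- setNames(pattern_alpha[part$patterns], part$labels)
  guessing <- c(0.27, 0.57, 0.07, 0.07, 0.08, 0.11, 0.20, 0.09, 0.09, 0.20,
                0.08, 0.07, 0.12, 0.08, 0.27, 0.23, 0.04, 0.03, 0.12, 0.07,
                0.13, 0.19, 0.02, 0.18, 0.08, 0.03, 0.03)
  parameter_set(eta = eta, cs = cs, alpha = alpha, guessing = guessing,
                partition = part)
}
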