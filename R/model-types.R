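# Domain types for the reduced sagittal-plane lower-limb model.
#
# The model is a kinematic tree rooted at the pelvis with three flexion
# degrees of freedom (hip, knee, ankle).  All positions are metres, expressed
# in segment-local frames with x anterior and y superior in the neutral
# (upright, all angles zero) pose.  Angles are radians, flexion positive.

#' Create a body segment
#'
#' @param name segment identifier.
#' @param mass segment mass (kg, > 0).
#' @param com_local centre-of-mass position in the segment frame (m, length 2).
#' @param inertia_zz moment of inertia about the COM, sagittal axis (kg m^2).
#' @param length segment length (m, > 0).
#' @param proximal_joint,distal_joint joint identifiers or `NA`.
#' @return an object of class `body_segment`.
#' @export
body_segment <- function(name, mass, com_local, inertia_zz, length,
                         proximal_joint = NA_character_,
                         distal_joint = NA_character_) {
  if (!is_scalar_number(mass) || mass <= 0) stopf("segment '%s': mass must be > 0", name)
  if (!is_scalar_number(length) || length <= 0) stopf("segment '%s': length must be > 0", name)
  if (!is_scalar_number(inertia_zz) || inertia_zz < 0) stopf("segment '%s': inertia_zz must be >= 0", name)
  structure(list(name = name, mass = mass, com_local = as.numeric(com_local),
                 inertia_zz = inertia_zz, length = length,
                 proximal_joint = proximal_joint, distal_joint = distal_joint),
            class = "body_segment")
}

#' Create a joint degree of freedom
#'
#' `axis_sign` maps the flexion-positive coordinate onto the mathematical
#' (+z, counter-clockwise with x anterior / y up) rotation of the child
#' relative to the parent: +1 for hip flexion and ankle dorsiflexion, -1 for
#' knee flexion.
#'
#' @param name joint identifier (e.g. `"knee_flexion"`).
#' @param parent,child segment identifiers.
#' @param axis_sign +1 or -1 (see details).
#' @param range permissible angle range (rad, length 2).
#' @param location_parent joint centre in the parent segment frame (m).
#' @return an object of class `joint_dof`.
#' @export
joint_dof <- function(name, parent, child, axis_sign, range = c(-pi / 2, pi),
                      location_parent = c(0, 0)) {
  stopifnot(axis_sign %in% c(-1, 1), length(range) == 2L, range[1] < range[2])
  structure(list(name = name, parent = parent, child = child,
                 axis_sign = axis_sign, range = as.numeric(range),
                 location_parent = as.numeric(location_parent)),
            class = "joint_dof")
}

#' Create a muscle path point
#'
#' @param segment segment the point is fixed to.
#' @param position_local coordinates in the segment frame (m, length 2).
#' @param role one of `"origin"`, `"via"`, `"insertion"`.
#' @return an object of class `path_point`.
#' @export
path_point <- function(segment, position_local, role = c("via", "origin", "insertion")) {
  role <- match.arg(role)
  structure(list(segment = segment, position_local = as.numeric(position_local),
                 role = role), class = "path_point")
}

#' Create a muscle-tendon unit
#'
#' A Hill-type actuator: maximum isometric force `mif` (N), tendon slack
#' length `tsl` (m), pennation angle at optimal fiber length `pen_opt` (rad),
#' optimal fiber length `l_opt` (m), and a geometric pathway given as an
#' ordered list of [path_point()]s (first point role `origin`, last
#' `insertion`, interior points `via`).
#'
#' @param name muscle identifier.
#' @param mif maximum isometric force (N, > 0).
#' @param tsl tendon slack length (m, > 0).
#' @param pen_opt pennation angle at optimal fiber length (rad, in [0, pi/2)).
#' @param l_opt optimal fiber length (m, > 0).
#' @param pathway list of [path_point()] objects.
#' @return an object of class `mtu`.
#' @export
mtu <- function(name, mif, tsl, pen_opt, l_opt, pathway) {
  if (!is_scalar_number(mif) || mif <= 0) stopf("muscle '%s': mif must be > 0", name)
  if (!is_scalar_number(tsl) || tsl <= 0) stopf("muscle '%s': tsl must be > 0", name)
  if (!is_scalar_number(l_opt) || l_opt <= 0) stopf("muscle '%s': l_opt must be > 0", name)
  if (!is_scalar_number(pen_opt) || pen_opt < 0 || pen_opt >= pi / 2)
    stopf("muscle '%s': pen_opt must be in [0, pi/2)", name)
  if (length(pathway) < 2L) stopf("muscle '%s': pathway needs >= 2 points", name)
  roles <- vapply(pathway, `[[`, "", "role")
  if (roles[1] != "origin" || roles[length(roles)] != "insertion" ||
      any(roles[-c(1, length(roles))] != "via"))
    stopf("muscle '%s': pathway roles must be origin, via*, insertion", name)
  segs <- vapply(pathway, `[[`, "", "segment")
  if (length(unique(segs)) < 2L)
    stopf("muscle '%s': pathway must touch >= 2 distinct segments", name)
  structure(list(name = name, mif = mif, tsl = tsl, pen_opt = pen_opt,
                 l_opt = l_opt, pathway = pathway), class = "mtu")
}

#' Create a muscle group
#'
#' Groups mirror the probabilistic study design: the full lower-limb set, the
#' uni-/biarticular knee extensors and flexors, hip and ankle muscles, and the
#' knee-hip and knee-ankle biarticular subsets.
#'
#' @param name group identifier.
#' @param members character vector of muscle names.
#' @return an object of class `muscle_group`.
#' @export
muscle_group <- function(name, members) {
  structure(list(name = name, members = unique(as.character(members))),
            class = "muscle_group")
}

#' Assemble a lower-limb model
#'
#' @param segments list of [body_segment()]s (first segment is the root).
#' @param dofs list of [joint_dof()]s forming a tree rooted at the pelvis.
#' @param muscles list of [mtu()]s.
#' @param groups list of [muscle_group()]s.
#' @param subject_mass total subject mass (kg).
#' @param subject_height subject stature (m).
#' @param markers optional data.frame of virtual markers with columns
#'   `name`, `segment`, `x`, `y` (m, segment frame), used by inverse
#'   kinematics and the TRC writer.
#' @param provenance free-form provenance tag (`"baseline"` or a perturbed
#'   iteration label).
#' @return an object of class `lowerlimb_model`.
#' @export
lowerlimb_model <- function(segments, dofs, muscles, groups,
                            subject_mass, subject_height,
                            markers = NULL, provenance = "baseline") {
  m <- structure(list(segments = segments, dofs = dofs, muscles = muscles,
                      groups = groups, subject_mass = subject_mass,
                      subject_height = subject_height, markers = markers,
                      provenance = provenance),
                 class = "lowerlimb_model")
  names(m$segments) <- vapply(segments, `[[`, "", "name")
  names(m$dofs) <- vapply(dofs, `[[`, "", "name")
  names(m$muscles) <- vapply(muscles, `[[`, "", "name")
  names(m$groups) <- vapply(groups, `[[`, "", "name")
  validate_model(m)
  m
}

#' Validate a lower-limb model
#'
#' Checks cross-references, pathway roles, the tree structure of the joint
#' graph, and that group memberships are subsets of the lower-limb set.
#'
#' @param model a [lowerlimb_model()].
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  seg_names <- names(model$segments)
  for (d in model$dofs) {
    if (!(d$parent %in% seg_names)) stopf("dof '%s': unknown parent '%s'", d$name, d$parent)
    if (!(d$child %in% seg_names)) stopf("dof '%s': unknown child '%s'", d$name, d$child)
  }
  # tree rooted at the first segment: each non-root segment is the child of
  # exactly one dof
  children <- vapply(model$dofs, `[[`, "", "child")
  if (anyDuplicated(children)) stopf("joint graph is not a tree: duplicated child")
  non_root <- setdiff(seg_names, seg_names[1])
  if (!setequal(children, non_root))
    stopf("joint graph must connect every non-root segment exactly once")
  for (mu in model$muscles) {
    for (p in mu$pathway)
      if (!(p$segment %in% seg_names))
        stopf("muscle '%s': path point on unknown segment '%s'", mu$name, p$segment)
  }
  msc_names <- names(model$muscles)
  for (g in model$groups) {
    unknown <- setdiff(g$members, msc_names)
    if (length(unknown))
      stopf("group '%s': unknown muscles %s", g$name, paste(unknown, collapse = ", "))
  }
  if (!is.null(model$groups$lower_limb)) {
    ll <- model$groups$lower_limb$members
    for (g in model$groups)
      if (g$name != "lower_limb" && length(setdiff(g$members, ll)))
        stopf("group '%s' is not a subset of lower_limb", g$name)
  }
  if (!is_scalar_number(model$subject_mass) || model$subject_mass <= 0)
    stopf("subject_mass must be > 0")
  invisible(model)
}

#' @export
print.lowerlimb_model <- function(x, ...) {
  cat(sprintf("<lowerlimb_model> %s: %d segments, %d dofs, %d muscles, %.1f kg, %.2f m\n",
              x$provenance, length(x$segments), length(x$dofs),
              length(x$muscles), x$subject_mass, x$subject_height))
  invisible(x)
}

#' Muscle names belonging to a group
#'
#' @param model a [lowerlimb_model()].
#' @param group group name.
#' @return character vector of muscle names.
#' @export
group_members <- function(model, group) {
  g <- model$groups[[group]]
  if (is.null(g)) stopf("unknown muscle group '%s'", group)
  g$members
}
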