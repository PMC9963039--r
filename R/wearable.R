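# Idealized wearable channels: what a trunk IMU and pressure insoles would
# report, derived noise-free from laboratory-style 3D signals. The trunk
# condition has 9 channels (3 orientation angles, 3 gravity-free linear
# accelerations, 3 angular velocities, global frame); the force block adds 6
# (per foot: foot-normal force, anteroposterior and mediolateral centre of
# pressure in the foot frame).

#' Foot coordinate frame
#'
#' @param origin global position of the foot-frame origin, m (length 3).
#' @param long_axis unit vector along the foot's long axis (anteroposterior).
#' @param normal unit vector normal to the foot sole (pointing up for a flat
#'   foot). Must be orthogonal to `long_axis`.
#' @return A list of class `foot_pose` with fields `origin`, `long_axis`,
#'   `normal` and the derived in-plane `ml_axis = normal x long_axis`.
#' @export
#' @examples
#' foot_pose()                      # flat foot, long axis along +x
foot_pose <- function(origin = c(0, 0, 0),
                      long_axis = c(1, 0, 0),
                      normal = c(0, 0, 1)) {
  stopifnot(length(origin) == 3, length(long_axis) == 3, length(normal) == 3)
  if (abs(sum(long_axis^2) - 1) > 1e-9 || abs(sum(normal^2) - 1) > 1e-9) {
    stop_config("foot axes must be unit vectors (|norm - 1| <= 1e-9)")
  }
  if (abs(sum(long_axis * normal)) > 1e-9) {
    stop_config("foot normal must be orthogonal to the long axis")
  }
  ml <- c(normal[2] * long_axis[3] - normal[3] * long_axis[2],
          normal[3] * long_axis[1] - normal[1] * long_axis[3],
          normal[1] * long_axis[2] - normal[2] * long_axis[1])
  structure(list(origin = origin, long_axis = long_axis, normal = normal,
                 ml_axis = ml), class = "foot_pose")
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    x
  } else {
    stopifnot(length(x) == 3)
    matrix(x, ncol = 3)
  }
}

#' Project a 3D ground reaction force onto the foot normal
#'
#' The pressure-insole force channel: the component of the 3D ground
#' reaction force along the foot's normal vector (shear is discarded).
#' Positive values are compressive support.
#'
#' @param grf_3d numeric length-3 vector or an n x 3 matrix of forces, N.
#' @param pose a [foot_pose()].
#' @return numeric scalar or vector of foot-normal forces, N.
#' @export
#' @examples
#' project_grf_to_foot_normal(c(100, 0, 700), foot_pose())  # 700
project_grf_to_foot_normal <- function(grf_3d, pose) {
  stopifnot(inherits(pose, "foot_pose"))
  drop(as_xyz_matrix(grf_3d) %*% pose$normal)
}

#' Transform a global centre of pressure into the foot frame
#'
#' AP is the projection of (COP - origin) on the foot long axis, ML the
#' projection on the in-plane axis orthogonal to it (`normal x long_axis`).
#'
#' @param cop_global numeric length-3 vector or n x 3 matrix, m.
#' @param pose a [foot_pose()].
#' @return n x 2 matrix with columns `ap`, `ml` (a 1 x 2 matrix for a single
#'   point), m.
#' @export
transform_cop_to_foot_frame <- function(cop_global, pose) {
  stopifnot(inherits(pose, "foot_pose"))
  rel <- sweep(as_xyz_matrix(cop_global), 2, pose$origin)
  out <- cbind(ap = drop(rel %*% pose$long_axis),
               ml = drop(rel %*% pose$ml_axis))
  out
}

#' Back-transform foot-frame COP to global coordinates
#'
#' Inverse of [transform_cop_to_foot_frame()] for in-plane points.
#'
#' @param cop_foot n x 2 matrix (or length-2 vector) of `ap`, `ml`, m.
#' @param pose a [foot_pose()].
#' @return n x 3 matrix of global coordinates.
#' @export
transform_cop_to_global <- function(cop_foot, pose) {
  stopifnot(inherits(pose, "foot_pose"))
  if (!is.matrix(cop_foot)) cop_foot <- matrix(cop_foot, ncol = 2)
  t(apply(cop_foot, 1, function(p) {
    pose$origin + p[1] * pose$long_axis + p[2] * pose$ml_axis
  }))
}

#' Extract the 9 idealized trunk channels from sampled kinematics
#'
#' Given uniformly sampled trunk orientation angles (intrinsic X-Y-Z,
#' degrees, global frame) and the global position of a trunk-mounted point,
#' returns the 9 channels in the fixed order angles(3), linear
#' accelerations(3), angular velocities(3). Angular velocity is obtained by
#' central differences of the angles (one-sided at the endpoints); linear
#' acceleration by twice-applied central differences of the position, i.e.
#' gravity-free kinematic acceleration as approximated from motion capture.
#'
#' @param time numeric vector, s, strictly increasing and uniform.
#' @param angles n x 3 matrix of orientation angles, degrees.
#' @param positions n x 3 matrix of the trunk point's global position, m
#'   (optional; if omitted the acceleration channels are returned as zero).
#' @return n x 9 numeric matrix with columns `angle_1..3`, `acc_1..3`
#'   (m/s^2), `angvel_1..3` (deg/s).
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' ang <- cbind(30 * sin(2 * pi * t), 0, 0)
#' ch <- extract_trunk_channels(t, ang)
#' max(ch[, "angvel_1"])            # close to 60 * pi
extract_trunk_channels <- function(time, angles, positions = NULL) {
  dt <- check_uniform_time(time)
  angles <- as.matrix(angles)
  stopifnot(ncol(angles) == 3, nrow(angles) == length(time))
  angvel <- apply(angles, 2, central_diff, dt = dt)
  if (is.null(positions)) {
    acc <- matrix(0, nrow(angles), 3)
  } else {
    positions <- as.matrix(positions)
    stopifnot(ncol(positions) == 3, nrow(positions) == length(time))
    acc <- apply(positions, 2, function(p) central_diff(central_diff(p, dt), dt))
  }
  out <- cbind(angles, acc, angvel)
  colnames(out) <- c(paste0("angle_", 1:3), paste0("acc_", 1:3),
                     paste0("angvel_", 1:3))
  out
}

# channel-name contracts shared by the feature builder and validators
trunk_channel_names <- function() {
  c("trunk_angle_flexion", "trunk_angle_lateral", "trunk_angle_twist",
    "trunk_acc_ap", "trunk_acc_ml", "trunk_acc_vert",
    "trunk_angvel_flexion", "trunk_angvel_lateral", "trunk_angvel_twist")
}

force_channel_names <- function() {
  c("foot_force_left", "foot_force_right",
    "cop_ap_left", "cop_ml_left", "cop_ap_right", "cop_ml_right")
}
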