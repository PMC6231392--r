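# Shared fixtures for the test suite. Everything is generated in code at
# test time; nothing is read from disk.

# identity pose for the synthetic projector
pf_id_pose <- list(scale = 1, pitch = 0, yaw = 0, roll = 0, tx = 0, ty = 0)

# project the canonical template (optionally deformed) into QVGA frame pixels
project_template <- function(expression = "neutral", amplitude = 0,
                             pose = pf_id_pose, centre = c(160, 120),
                             base_scale = 0.62) {
  tpl <- face_template()
  field <- expression_field(expression) * amplitude
  painface:::pf_project_points(cbind(tpl$xy + field, tpl$z), pose, centre,
                               base_scale)
}

# render one annotated frame and return frame + landmarks
make_frame <- function(expression = "neutral", amplitude = 0,
                       pose = pf_id_pose, gain = 1, noise_sd = 0) {
  pts <- project_template(expression, amplitude, pose)
  px <- render_frame(pts, illumination = gain, noise_sd = noise_sd)
  list(frame = pf_frame(px), landmarks = pf_landmarks(pts))
}

# a short scripted synthetic video (neutral / other / pain)
make_video <- function(seed, other = "smile", frames_per_segment = 45L,
                       noise_sd = 2, amplitude = NULL) {
  set.seed(seed)
  amp <- if (is.null(amplitude)) stats::runif(2, 0.8, 1) else rep(amplitude, 2)
  scr <- expression_script(
    data.frame(expression = c("neutral", other, "pain"),
               duration = rep(frames_per_segment, 3L),
               amplitude = c(0, amp[1], amp[2])),
    seed = seed, noise_sd = noise_sd)
  suppressWarnings(generate_expression_sequence(scr))
}

# small trained landmark models (shape + patch) built from clean renders
make_models <- function(n_amp = c(0, 0.5, 1)) {
  crops <- list(); shapes <- list()
  cfg <- pipeline_config()
  for (e in c("neutral", "pain", "smile", "surprise", "angry")) {
    for (a in n_amp) {
      if (e == "neutral" && a > 0) next
      rec <- make_frame(e, a)
      cr <- detect_and_crop_face(rec$frame)
      crops[[length(crops) + 1]] <-
        enhance_crop(normalize_crop(cr), cfg$pointop)$pixels
      shapes[[length(shapes) + 1]] <-
        painface:::pf_to_crop_coords(rec$landmarks, cr$bbox)
    }
  }
  gpa <- procrustes_align(shapes)
  sm <- build_shape_model(gpa$aligned)
  pm <- build_patch_model(crops, shapes)
  list(shape = sm, patch = pm,
       tree = build_tree(rep(TRUE, 66), painface:::pf_vec_to_shape(sm$mean_shape)),
       crops = crops, shapes = shapes)
}
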