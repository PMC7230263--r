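test_that("solid-nodule shear profile is symmetric about the apex", {
  sp <- shear_profile(fld_solid40())
  expect_s3_class(sp, "shear_profile")
  expect_equal(nrow(sp), 181L)
  ## samples are mirror-symmetric in arc position
  expect_equal(sp$arc_position, -rev(sp$arc_position))
  asym <- max(abs(sp$shear_normalized - rev(sp$shear_normalized)))
  expect_lt(asym / attr(sp, "peak"), 0.05)
  ## normalization is elementwise raw / tau_w
  expect_equal(sp$shear_normalized,
               sp$shear_raw / attr(sp, "wall_shear"))
  ## all sampled surface positions are on the exposed surface (z >= 0)
  nod <- fld_solid40()$nodule
  expect_true(all(nod$z_center + nod$b * sin(sp$angle) >= -1e-12))
})

test_that("porous nodule experiences lower peak shear than solid at matched geometry", {
  ps <- attr(shear_profile(fld_solid40()), "peak")
  pp <- attr(shear_profile(fld_porous40()), "peak")
  expect_lt(pp, ps)
})

test_that("porous penetration flux enters upstream, exits downstream, and conserves mass", {
  fx <- flux_profile(fld_porous40())
  ## closed-surface mass conservation
  expect_lt(abs(attr(fx, "net_flux")) / attr(fx, "abs_flux"), 0.02)
  ## hemisphere pattern (away from the apex and base where flux ~ 0)
  up <- fx$arc_position < -0.15 & fx$arc_position > -0.9
  dn <- fx$arc_position > 0.15 & fx$arc_position < 0.9
  expect_true(all(fx$normal_flux[up] > 0))
  expect_true(all(fx$normal_flux[dn] < 0))
  ## antisymmetry of the flux for the symmetric nodule
  expect_lt(max(abs(fx$normal_flux + rev(fx$normal_flux))) /
              attr(fx, "scale_velocity"), 0.05)
  ## zero flux where the flow runs parallel to the surface, i.e. at the
  ## shear maximum (within sampling resolution of the discrete profiles)
  sp <- shear_profile(fld_porous40())
  s_zero <- fx$arc_position[which.min(abs(fx$normal_flux))]
  s_max <- sp$arc_position[which.max(sp$shear_normalized)]
  expect_lt(abs(s_zero - s_max), 0.15)
  expect_gt(sp$shear_normalized[which.min(abs(sp$arc_position - s_zero))],
            0.9 * attr(sp, "peak"))
})

test_that("solid-limit consistency: vanishing permeability recovers the solid profile", {
  ffl <- solve_channel_flow(test_geom(), fluid_properties(),
                            nodule_geometry(a = 40e-6),
                            porous_properties(permeability = 1e-18),
                            mesh_spec(4e-6))
  pl <- attr(shear_profile(ffl), "peak")
  ps <- attr(shear_profile(fld_solid40()), "peak")
  expect_lt(abs(pl - ps) / ps, 0.10)
})

test_that("profile functions reject fields without the required nodule", {
  expect_error(shear_profile(fld_empty()), "nodule")
  expect_error(flux_profile(fld_empty()), "nodule")
  expect_error(flux_profile(fld_solid40()), "porous")
})

test_that("geometry sweep is consistent with direct solves and deterministic", {
  msh <- mesh_spec(4e-6)
  sw <- sweep_nodule_geometry(a_values = 40e-6, porous_states = FALSE,
                              geom = test_geom(), mesh = msh)
  expect_equal(nrow(sw), 1L)
  expect_false(sw$failed)
  expect_equal(sw$peak_shear_normalized,
               attr(shear_profile(fld_solid40()), "peak"))
  sw2 <- sweep_nodule_geometry(a_values = 40e-6, porous_states = FALSE,
                               geom = test_geom(), mesh = msh)
  expect_identical(sw, sw2)
  ## failures are reported per row, not thrown
  swf <- sweep_nodule_geometry(a_values = c(30e-6, 40e-6),
                               porous_states = FALSE,
                               geom = test_geom(), mesh = msh)
  expect_true(swf$failed[1])   # a < b is invalid
  expect_false(swf$failed[2])
  expect_match(swf$message[1], "semi-axes")
})
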