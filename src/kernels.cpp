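#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Face type codes mirrored from R/mesh.R
static const int F_EXT = 0, F_INT = 1, F_WALL = 2, F_INLET = 3, F_OUT1 = 4;

// MAC bilinear interpolation of one staggered component.
// Component grid: value(i, j) at x = x0 + (i + offx) * h, y = y0 + (j + offy) * h.
static inline double interp_component(const NumericMatrix& a,
                                      double x, double y,
                                      double x0, double y0, double h,
                                      double offx, double offy) {
  int nx = a.nrow(), ny = a.ncol();
  double gx = (x - x0) / h - offx;
  double gy = (y - y0) / h - offy;
  int i0 = (int)std::floor(gx);
  int j0 = (int)std::floor(gy);
  double fx = gx - i0, fy = gy - j0;
  if (i0 < 0) { i0 = 0; fx = 0.0; }
  if (i0 > nx - 2) { i0 = nx - 2; fx = 1.0; }
  if (j0 < 0) { j0 = 0; fy = 0.0; }
  if (j0 > ny - 2) { j0 = ny - 2; fy = 1.0; }
  return (1 - fx) * (1 - fy) * a(i0, j0) + fx * (1 - fy) * a(i0 + 1, j0) +
         (1 - fx) * fy * a(i0, j0 + 1) + fx * fy * a(i0 + 1, j0 + 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_interp_velocity(NumericVector xs, NumericVector ys,
                                  NumericMatrix u, NumericMatrix v,
                                  double x0, double y0, double h) {
  int n = xs.size();
  NumericMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    out(k, 0) = interp_component(u, xs[k], ys[k], x0, y0, h, 0.0, 0.5);
    out(k, 1) = interp_component(v, xs[k], ys[k], x0, y0, h, 0.5, 0.0);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_interp_cellfield(NumericVector xs, NumericVector ys,
                                   NumericMatrix f,
                                   double x0, double y0, double h) {
  int n = xs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = interp_component(f, xs[k], ys[k], x0, y0, h, 0.5, 0.5);
  return out;
}

// Momentum predictor: central convection + central diffusion + pressure
// gradient, forward Euler.  Tangential ghosts across walls use the no-slip
// mirror (-u).  Outlet faces copy the upstream predictor value (zero
// gradient); the projection then adjusts their flux through the p = 0 ghost.
// Returns the divergence of the predictor field over active cells.
// [[Rcpp::export]]
List cpp_predict(NumericMatrix u, NumericMatrix v, NumericMatrix q,
                 IntegerMatrix uType, IntegerMatrix vType,
                 IntegerMatrix uSign, IntegerMatrix vSign,
                 IntegerMatrix cellIdx, int nAct,
                 double h, double dt, double nu, bool explicit_visc) {
  if (!explicit_visc) nu = 0.0;  // diffusion handled implicitly by the caller
  int nxp1 = u.nrow(), ny = u.ncol();
  int nx = nxp1 - 1;
  NumericMatrix us(clone(u)), vs(clone(v));

  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nxp1; ++i) {
      if (uType(i, j) != F_INT) continue;
      double uc = u(i, j);
      double uE = u(i + 1, j), uW = u(i - 1, j);
      double uN = (j + 1 <= ny - 1 && uType(i, j + 1) != F_EXT) ? u(i, j + 1) : -uc;
      double uS = (j - 1 >= 0 && uType(i, j - 1) != F_EXT) ? u(i, j - 1) : -uc;
      double vnw = v(i - 1, j + 1), vne = v(i, j + 1);
      double vsw = v(i - 1, j),     vse = v(i, j);
      double ue = 0.5 * (uc + uE), uw = 0.5 * (uW + uc);
      double vn = 0.5 * (vnw + vne), vso = 0.5 * (vsw + vse);
      double un = 0.5 * (uc + uN), uso = 0.5 * (uS + uc);
      double adv = (ue * ue - uw * uw) / h + (vn * un - vso * uso) / h;
      double lap = (uE - 2.0 * uc + uW + uN - 2.0 * uc + uS) / (h * h);
      double gq = (q(i, j) - q(i - 1, j)) / h;
      us(i, j) = uc + dt * (-adv - gq + nu * lap);
    }
  }
  for (int j = 0; j < ny + 1; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (vType(i, j) != F_INT) continue;
      double vc = v(i, j);
      double vN = v(i, j + 1), vS = v(i, j - 1);
      double vE = (i + 1 <= nx - 1 && vType(i + 1, j) != F_EXT) ? v(i + 1, j) : -vc;
      double vW = (i - 1 >= 0 && vType(i - 1, j) != F_EXT) ? v(i - 1, j) : -vc;
      double une = u(i + 1, j), unw = u(i, j);
      double use_ = u(i + 1, j - 1), usw = u(i, j - 1);
      double vn = 0.5 * (vc + vN), vso = 0.5 * (vS + vc);
      double ue = 0.5 * (une + use_), uw = 0.5 * (unw + usw);
      double ve = 0.5 * (vc + vE), vwst = 0.5 * (vW + vc);
      double adv = (ue * ve - uw * vwst) / h + (vn * vn - vso * vso) / h;
      double lap = (vE - 2.0 * vc + vW + vN - 2.0 * vc + vS) / (h * h);
      double gq = (q(i, j) - q(i, j - 1)) / h;
      vs(i, j) = vc + dt * (-adv - gq + nu * lap);
    }
  }
  // outlet faces: zero-gradient copy of the upstream predictor value
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nxp1; ++i)
      if (uType(i, j) >= F_OUT1)
        us(i, j) = (uSign(i, j) == 1) ? us(i - 1, j) : us(i + 1, j);
  for (int j = 0; j < ny + 1; ++j)
    for (int i = 0; i < nx; ++i)
      if (vType(i, j) >= F_OUT1)
        vs(i, j) = (vSign(i, j) == 1) ? vs(i, j - 1) : vs(i, j + 1);

  NumericVector div(nAct);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int id = cellIdx(i, j);
      if (id > 0)
        div[id - 1] = (us(i + 1, j) - us(i, j)) / h + (vs(i, j + 1) - vs(i, j)) / h;
    }
  return List::create(_["us"] = us, _["vs"] = vs, _["div"] = div);
}

// [[Rcpp::export]]
NumericVector cpp_divergence(NumericMatrix us, NumericMatrix vs,
                             IntegerMatrix cellIdx, int nAct, double h) {
  int nx = us.nrow() - 1, ny = us.ncol();
  NumericVector div(nAct);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int id = cellIdx(i, j);
      if (id > 0)
        div[id - 1] = (us(i + 1, j) - us(i, j)) / h + (vs(i, j + 1) - vs(i, j)) / h;
    }
  return div;
}

// Projection correction: subtract dt * grad(phi) on interior faces and on
// outlet faces (phi = 0 ghost there).  Modifies us / vs in place.
// [[Rcpp::export]]
void cpp_correct(NumericMatrix us, NumericMatrix vs, NumericVector phi,
                 IntegerMatrix uType, IntegerMatrix vType,
                 IntegerMatrix uSign, IntegerMatrix vSign,
                 IntegerMatrix cellIdx, double h, double dt) {
  int nxp1 = us.nrow(), ny = us.ncol();
  int nx = nxp1 - 1;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nxp1; ++i) {
      int t = uType(i, j);
      if (t == F_INT) {
        double pe = phi[cellIdx(i, j) - 1], pw = phi[cellIdx(i - 1, j) - 1];
        us(i, j) -= dt * (pe - pw) / h;
      } else if (t >= F_OUT1) {
        if (uSign(i, j) == 1)
          us(i, j) -= dt * (0.0 - phi[cellIdx(i - 1, j) - 1]) / h;
        else
          us(i, j) -= dt * (phi[cellIdx(i, j) - 1] - 0.0) / h;
      }
    }
  }
  for (int j = 0; j < ny + 1; ++j) {
    for (int i = 0; i < nx; ++i) {
      int t = vType(i, j);
      if (t == F_INT) {
        double pn = phi[cellIdx(i, j) - 1], ps = phi[cellIdx(i, j - 1) - 1];
        vs(i, j) -= dt * (pn - ps) / h;
      } else if (t >= F_OUT1) {
        if (vSign(i, j) == 1)
          vs(i, j) -= dt * (0.0 - phi[cellIdx(i, j - 1) - 1]) / h;
        else
          vs(i, j) -= dt * (phi[cellIdx(i, j) - 1] - 0.0) / h;
      }
    }
  }
}

// Distance from cell centres to the nearest *discrete* wall face (the
// staircase boundary where the discrete velocity vanishes), computed exactly
// within a neighbourhood of `reach` cells of each wall face; +inf elsewhere.
// Wall-proximity tests against this surface are consistent with the flow
// field; testing against the exact outline instead would flag particles that
// are still inside staircase fluid.
// [[Rcpp::export]]
NumericMatrix cpp_staircase_distance(IntegerMatrix uType, IntegerMatrix vType,
                                     double h, int reach) {
  int nxp1 = uType.nrow(), ny = uType.ncol();
  int nx = nxp1 - 1;
  NumericMatrix d(nx, ny);
  std::fill(d.begin(), d.end(), R_PosInf);
  auto upd = [&](double segx0, double segy0, double segx1, double segy1,
                 int ic0, int jc0) {
    for (int jc = jc0 - reach; jc <= jc0 + reach; ++jc) {
      if (jc < 0 || jc >= ny) continue;
      for (int ic = ic0 - reach; ic <= ic0 + reach; ++ic) {
        if (ic < 0 || ic >= nx) continue;
        double px = (ic + 0.5) * h, py = (jc + 0.5) * h;
        double vx = segx1 - segx0, vy = segy1 - segy0;
        double t = ((px - segx0) * vx + (py - segy0) * vy) / (vx * vx + vy * vy);
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double dx = px - (segx0 + t * vx), dy = py - (segy0 + t * vy);
        double dd = std::sqrt(dx * dx + dy * dy);
        if (dd < d(ic, jc)) d(ic, jc) = dd;
      }
    }
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nxp1; ++i)
      if (uType(i, j) == F_WALL)
        upd(i * h, j * h, i * h, (j + 1) * h, i, j);
  for (int j = 0; j < ny + 1; ++j)
    for (int i = 0; i < nx; ++i)
      if (vType(i, j) == F_WALL)
        upd(i * h, j * h, (i + 1) * h, j * h, i, j);
  return d;
}

// One-way-coupled Lagrangian tracker.  Drag is treated semi-analytically:
// over a step the fluid velocity (sampled at the midpoint) and the
// Schiller-Naumann correction factor are frozen, and the linear drag ODE
// m dv/dt = (u_f - v)/tau_eff * m + g_eff is integrated exactly.  This keeps
// micrometre particles (tau_p ~ 8 us) stable at convective time steps.
//
// status codes: 1 exited_outlet_1, 2 exited_outlet_2, 3 wall_contact,
//               4 max_time, 5 error_outside
// Two-level (global + carina zoom patch) field sampler used by the tracker.
struct CompositeField {
  const NumericMatrix *u, *v, *dist;
  double x0, y0, h;
  const NumericMatrix *zu, *zv, *zdist;
  double zx0, zy0, zh;
  double bx0, bx1, by0, by1;   // zoom interior box (with safety pad)
  bool has_zoom;
  inline bool in_zoom(double x, double y) const {
    return has_zoom && x > bx0 && x < bx1 && y > by0 && y < by1;
  }
  inline double U(double x, double y) const {
    return in_zoom(x, y) ? interp_component(*zu, x, y, zx0, zy0, zh, 0.0, 0.5)
                         : interp_component(*u, x, y, x0, y0, h, 0.0, 0.5);
  }
  inline double V(double x, double y) const {
    return in_zoom(x, y) ? interp_component(*zv, x, y, zx0, zy0, zh, 0.5, 0.0)
                         : interp_component(*v, x, y, x0, y0, h, 0.5, 0.0);
  }
  inline double D(double x, double y) const {
    return in_zoom(x, y) ? interp_component(*zdist, x, y, zx0, zy0, zh, 0.5, 0.5)
                         : interp_component(*dist, x, y, x0, y0, h, 0.5, 0.5);
  }
};

// [[Rcpp::export]]
List cpp_track(NumericVector sx, NumericVector sy,
               NumericMatrix u, NumericMatrix v, NumericMatrix dist,
               double x0, double y0, double h,
               double tau_p, double repc, bool schiller,
               double gx, double gy,
               double dt, double max_time, double clearance,
               double apex_x, double apex_y, double region_r,
               NumericMatrix outlets, // rows: ox, oy, dx, dy, L
               IntegerVector store_id, int store_every,
               int wall_mode,        // 0 = slide (impermeable), 1 = arrest
               bool has_zoom,
               NumericMatrix zu, NumericMatrix zv, NumericMatrix zdist,
               double zx0, double zy0, double zh, NumericVector zbox) {
  int n = sx.size();
  int nout = outlets.nrow();
  IntegerVector status(n), nsteps(n), n_touch(n);
  LogicalVector touch_region(n);
  NumericVector exit_time(n), min_dist(n), residence(n), max_rep(n);
  NumericVector fx(n), fy(n);
  std::vector<double> px, py, pt, pu, pv;
  std::vector<int> pid;
  bool have_apex = R_finite(apex_x);
  double r2 = region_r * region_r;

  CompositeField F;
  F.u = &u; F.v = &v; F.dist = &dist; F.x0 = x0; F.y0 = y0; F.h = h;
  F.zu = &zu; F.zv = &zv; F.zdist = &zdist;
  F.zx0 = zx0; F.zy0 = zy0; F.zh = zh;
  F.has_zoom = has_zoom;
  if (has_zoom) {
    F.bx0 = zbox[0]; F.bx1 = zbox[1]; F.by0 = zbox[2]; F.by1 = zbox[3];
  } else {
    F.bx0 = F.bx1 = F.by0 = F.by1 = 0.0;
  }

  for (int k = 0; k < n; ++k) {
    double x = sx[k], y = sy[k];
    double vel0x = F.U(x, y);
    double vel0y = F.V(x, y);
    double vpx = vel0x, vpy = vel0y;
    double t = 0.0, mind = R_PosInf, res = 0.0, mrep = 0.0;
    int st = 0; long step = 0;
    bool storing = store_id[k] > 0;
    if (storing) {
      pid.push_back(store_id[k]); pt.push_back(t);
      px.push_back(x); py.push_back(y); pu.push_back(vpx); pv.push_back(vpy);
    }
    while (st == 0) {
      // midpoint field sample
      double xm = x + 0.5 * dt * vpx, ym = y + 0.5 * dt * vpy;
      double ufx = F.U(xm, ym);
      double ufy = F.V(xm, ym);
      double slx = ufx - vpx, sly = ufy - vpy;
      double slip = std::sqrt(slx * slx + sly * sly);
      double rep = repc * slip;
      if (rep > mrep) mrep = rep;
      double f = (schiller && rep > 0.0) ? 1.0 + 0.15 * std::pow(rep, 0.687) : 1.0;
      double tau = tau_p / f;
      double E = std::exp(-dt / tau);
      double Ax = ufx + gx * tau, Ay = ufy + gy * tau;
      double vnx = Ax + (vpx - Ax) * E;
      double vny = Ay + (vpy - Ay) * E;
      double xn = x + Ax * dt + tau * (vpx - Ax) * (1.0 - E);
      double yn = y + Ay * dt + tau * (vpy - Ay) * (1.0 - E);

      if (have_apex) {
        // min distance from the step segment to the apex, exact
        double ex = xn - x, ey = yn - y;
        double L2 = ex * ex + ey * ey;
        double ts = 0.0;
        if (L2 > 0.0) {
          ts = ((apex_x - x) * ex + (apex_y - y) * ey) / L2;
          if (ts < 0.0) ts = 0.0; else if (ts > 1.0) ts = 1.0;
        }
        double ddx = x + ts * ex - apex_x, ddy = y + ts * ey - apex_y;
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        if (d < mind) mind = d;
        // residence: fraction of the segment inside the carina disc
        if (d < region_r) {
          double ax = x - apex_x, ay = y - apex_y;
          if (L2 > 0.0) {
            double b = (ax * ex + ay * ey) / L2;
            double c = (ax * ax + ay * ay - r2) / L2;
            double disc = b * b - c;
            if (disc > 0.0) {
              double sq = std::sqrt(disc);
              double s1 = -b - sq, s2 = -b + sq;
              if (s1 < 0.0) s1 = 0.0;
              if (s2 > 1.0) s2 = 1.0;
              if (s2 > s1) res += (s2 - s1) * dt;
            }
          } else {
            res += dt;
          }
        }
      }

      // terminal-status checks
      for (int o = 0; o < nout; ++o) {
        double s_along = (xn - outlets(o, 0)) * outlets(o, 2) +
                         (yn - outlets(o, 1)) * outlets(o, 3);
        if (s_along >= outlets(o, 4)) { st = o + 1; break; }
      }
      if (st == 0) {
        double wd = F.D(xn, yn);
        if (wd < clearance) {
          ++n_touch[k];
          bool in_region = have_apex &&
            ((xn - apex_x) * (xn - apex_x) + (yn - apex_y) * (yn - apex_y)
               <= r2);
          if (in_region) touch_region[k] = true;
          if (wall_mode == 1) {
            st = 3;                          // arrest: freeze on contact
          } else {
            // impermeable slide: push back to the clearance surface along
            // the distance gradient and drop the inward normal velocity
            double del = 0.25 * (F.in_zoom(xn, yn) ? zh : h);
            double gxd = (F.D(xn + del, yn) - F.D(xn - del, yn)) / (2 * del);
            double gyd = (F.D(xn, yn + del) - F.D(xn, yn - del)) / (2 * del);
            double gn = std::sqrt(gxd * gxd + gyd * gyd);
            if (gn > 1e-12) {
              gxd /= gn; gyd /= gn;
              xn += (clearance - wd) * gxd;
              yn += (clearance - wd) * gyd;
              double vn_ = vnx * gxd + vny * gyd;
              if (vn_ < 0) { vnx -= vn_ * gxd; vny -= vn_ * gyd; }
            }
            if (F.D(xn, yn) < -0.5 * h)
              st = 5;                        // projection failed; escaped
          }
        } else if (wd < -0.5 * h) {
          st = 5;                            // escaped the domain
        }
      }
      x = xn; y = yn; vpx = vnx; vpy = vny; t += dt; ++step;
      if (st == 0 && t >= max_time) st = 4;
      if (storing && (st != 0 || step % store_every == 0)) {
        pid.push_back(store_id[k]); pt.push_back(t);
        px.push_back(x); py.push_back(y); pu.push_back(vpx); pv.push_back(vpy);
      }
    }
    status[k] = st; exit_time[k] = t; min_dist[k] = mind;
    residence[k] = res; max_rep[k] = mrep; nsteps[k] = (int)step;
    fx[k] = x; fy[k] = y;
  }

  return List::create(
    _["status"] = status, _["exit_time"] = exit_time,
    _["min_dist_apex"] = min_dist, _["residence"] = residence,
    _["max_rep"] = max_rep, _["n_steps"] = nsteps,
    _["x_end"] = fx, _["y_end"] = fy,
    _["n_wall_touch"] = n_touch, _["touch_in_region"] = touch_region,
    _["path"] = DataFrame::create(
      _["particle_id"] = wrap(pid), _["t"] = wrap(pt),
      _["x"] = wrap(px), _["y"] = wrap(py),
      _["u"] = wrap(pu), _["v"] = wrap(pv))
  );
}
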