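// Analytic benchmark surfaces and overdamped Langevin samplers.
// All energies in kcal/mol, lengths in nm (toy 2-D potentials use their
// own natural units), temperatures in Kelvin.  R's RNG is used throughout
// so trajectories are reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/(mol K)

// ---------------------------------------------------------------------------
// Surface representation
// ---------------------------------------------------------------------------

enum SurfType { DW1D = 1, MBROWN = 2, QUADBOWL = 3, GMIX = 4, CHANNELS = 5, MLP = 6 };

struct Surface {
  int type;
  int dim;
  // double_well_1d / channels_2d
  double h, h2;
  // quad_bowl_nd
  arma::vec kappa, center;
  // gaussian mixture wells (sym6d_wells and friends)
  arma::mat mix_centers;  // k x dim
  arma::vec mix_w;
  double mix_s, kT0;
  // mlp
  int feat;               // 0 identity, 1 symmetric (dim must be 6)
  arma::vec fmu, fsd, b1, b2, w3;
  arma::mat W1, W2;       // W1: nfeat x n1, W2: n1 x n2
  double b3, offset;
};

static Surface parse_surface(const List& spec) {
  Surface s;
  s.type = as<int>(spec["type_id"]);
  s.dim  = as<int>(spec["dim"]);
  s.h = s.h2 = 0.0; s.mix_s = 1.0; s.kT0 = 1.0; s.b3 = 0.0; s.offset = 0.0; s.feat = 0;
  switch (s.type) {
  case DW1D:
    s.h = as<double>(spec["h"]);
    break;
  case MBROWN:
    break;
  case QUADBOWL:
    s.kappa  = as<arma::vec>(spec["kappa"]);
    s.center = as<arma::vec>(spec["center"]);
    break;
  case GMIX:
    s.mix_centers = as<arma::mat>(spec["centers"]);
    s.mix_w       = as<arma::vec>(spec["weights"]);
    s.mix_s       = as<double>(spec["width"]);
    s.kT0         = as<double>(spec["kT"]);
    break;
  case CHANNELS:
    s.h  = as<double>(spec["h1"]);
    s.h2 = as<double>(spec["h2"]);
    break;
  case MLP:
    s.feat = as<int>(spec["feat"]);
    s.fmu  = as<arma::vec>(spec["fmu"]);
    s.fsd  = as<arma::vec>(spec["fsd"]);
    s.W1   = as<arma::mat>(spec["W1"]);
    s.b1   = as<arma::vec>(spec["b1"]);
    s.W2   = as<arma::mat>(spec["W2"]);
    s.b2   = as<arma::vec>(spec["b2"]);
    s.w3   = as<arma::vec>(spec["w3"]);
    s.b3   = as<double>(spec["b3"]);
    s.offset = as<double>(spec["offset"]);
    break;
  default:
    stop("unknown surface type id");
  }
  return s;
}

// Muller-Brown parameter set (literature-standard 4-term Gaussian form)
static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

// symmetric features for 6-D distance vectors:
// s(d) = (d1+d6, d1*d6, d2+d5, d2*d5, d3, d4)
static inline void sym_features(const arma::vec& d, arma::vec& f) {
  f[0] = d[0] + d[5];
  f[1] = d[0] * d[5];
  f[2] = d[1] + d[4];
  f[3] = d[1] * d[4];
  f[4] = d[2];
  f[5] = d[3];
}

static double surf_energy_grad(const Surface& s, const arma::vec& x, arma::vec& g) {
  switch (s.type) {
  case DW1D: {
    double u = x[0] * x[0] - 1.0;
    g[0] = 4.0 * s.h * x[0] * u;
    return s.h * u * u;
  }
  case MBROWN: {
    double V = 0.0, gx = 0.0, gy = 0.0;
    for (int k = 0; k < 4; ++k) {
      double dx = x[0] - MB_x0[k], dy = x[1] - MB_y0[k];
      double e = MB_A[k] * std::exp(MB_a[k]*dx*dx + MB_b[k]*dx*dy + MB_c[k]*dy*dy);
      V  += e;
      gx += e * (2.0*MB_a[k]*dx + MB_b[k]*dy);
      gy += e * (MB_b[k]*dx + 2.0*MB_c[k]*dy);
    }
    g[0] = gx; g[1] = gy;
    return V;
  }
  case QUADBOWL: {
    double V = 0.0;
    for (int i = 0; i < s.dim; ++i) {
      double dx = x[i] - s.center[i];
      V += 0.5 * s.kappa[i] * dx * dx;
      g[i] = s.kappa[i] * dx;
    }
    return V;
  }
  case GMIX: {
    // A = -kT0 log( sum_i w_i exp(-|x-c_i|^2 / (2 s^2)) ), log-sum-exp stabilised
    int k = s.mix_centers.n_rows;
    double s2 = s.mix_s * s.mix_s;
    arma::vec ex(k);
    double emax = -1e300;
    for (int i = 0; i < k; ++i) {
      double r2 = 0.0;
      for (int j = 0; j < s.dim; ++j) {
        double d = x[j] - s.mix_centers(i, j);
        r2 += d * d;
      }
      ex[i] = -r2 / (2.0 * s2);
      if (ex[i] > emax) emax = ex[i];
    }
    double rho = 0.0;
    for (int i = 0; i < k; ++i) { ex[i] = s.mix_w[i] * std::exp(ex[i] - emax); rho += ex[i]; }
    g.zeros();
    for (int i = 0; i < k; ++i) {
      double wi = ex[i] / rho;
      for (int j = 0; j < s.dim; ++j)
        g[j] += s.kT0 * wi * (x[j] - s.mix_centers(i, j)) / s2;
    }
    return -s.kT0 * (std::log(rho) + emax);
  }
  case CHANNELS: {
    // two symmetric channels along the unit circle between minima (+-1, 0)
    double u = x[0]*x[0] - 1.0;
    double v = x[0]*x[0] + x[1]*x[1] - 1.0;
    g[0] = 4.0 * s.h * x[0] * u + 4.0 * s.h2 * x[0] * v;
    g[1] = 4.0 * s.h2 * x[1] * v;
    return s.h * u * u + s.h2 * v * v;
  }
  case MLP: {
    int nf = s.fmu.n_elem;
    arma::vec f(nf);
    if (s.feat == 1) sym_features(x, f); else f = x;
    arma::vec z = (f - s.fmu) / s.fsd;
    arma::vec h1 = s.W1.t() * z + s.b1;
    arma::vec a1 = arma::tanh(h1);
    arma::vec h2 = s.W2.t() * a1 + s.b2;
    arma::vec a2 = arma::tanh(h2);
    double E = arma::dot(s.w3, a2) + s.b3 - s.offset;
    arma::vec gh2 = s.w3 % (1.0 - a2 % a2);
    arma::vec gh1 = (s.W2 * gh2) % (1.0 - a1 % a1);
    arma::vec gz  = s.W1 * gh1;
    arma::vec gf  = gz / s.fsd;
    if (s.feat == 1) {
      g[0] = gf[0] + x[5] * gf[1];
      g[5] = gf[0] + x[0] * gf[1];
      g[1] = gf[2] + x[4] * gf[3];
      g[4] = gf[2] + x[1] * gf[3];
      g[2] = gf[4];
      g[3] = gf[5];
    } else {
      g = gf;
    }
    return E;
  }
  }
  stop("unreachable");
}

// [[Rcpp::export]]
List eval_batch_cpp(List spec, arma::mat X, bool want_grad) {
  Surface s = parse_surface(spec);
  int n = X.n_rows;
  if ((int)X.n_cols != s.dim) stop("eval_batch: dimension mismatch");
  arma::vec E(n), g(s.dim);
  arma::mat G;
  if (want_grad) G.set_size(n, s.dim);
  arma::vec x(s.dim);
  for (int i = 0; i < n; ++i) {
    x = X.row(i).t();
    E[i] = surf_energy_grad(s, x, g);
    if (want_grad) G.row(i) = g.t();
  }
  NumericVector Ev(E.begin(), E.end());
  if (want_grad) return List::create(_["energy"] = Ev, _["grad"] = G);
  return List::create(_["energy"] = Ev);
}

// ---------------------------------------------------------------------------
// Overdamped Langevin with optional harmonic restraint
//   x <- x - (dt/gamma) * (grad A + kres*(x - cres)) + sqrt(2 kB T dt/gamma) * xi
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List langevin_cpp(List spec, arma::vec x0, int n_steps, double dt, double gamma,
                  double T, int save_stride, arma::vec kres, arma::vec cres,
                  arma::vec lower, arma::vec upper) {
  Surface s = parse_surface(spec);
  int dim = s.dim;
  arma::vec x = x0, g(dim);
  double noise = std::sqrt(2.0 * KB * T * dt / gamma);
  int n_save = n_steps / save_stride;
  arma::mat out(n_save, dim);
  arma::vec span = upper - lower;
  int isave = 0;
  for (int t = 1; t <= n_steps; ++t) {
    surf_energy_grad(s, x, g);
    for (int j = 0; j < dim; ++j) {
      double f = g[j] + kres[j] * (x[j] - cres[j]);
      x[j] += -dt / gamma * f + noise * norm_rand();
      if (x[j] < lower[j] - 10.0 * span[j] || x[j] > upper[j] + 10.0 * span[j] ||
          !std::isfinite(x[j]))
        stop("langevin instability at step %d (dt = %g too large?)", t, dt);
    }
    if (t % save_stride == 0) out.row(isave++) = x.t();
  }
  return List::create(_["samples"] = out, _["final"] = x);
}

// ---------------------------------------------------------------------------
// Metadynamics + TAMD on projection collective variables.
// Physical x at temperature T; extended z at Tbar tethered by kappa_ext;
// repulsive Gaussian hills deposited at z every deposit_stride steps.
// Soft harmonic walls keep z inside [zlo, zhi].
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List tamd_metad_cpp(List spec, arma::vec x0, arma::vec z0, arma::ivec cvdims,
                    double kappa_ext, double T, double Tbar,
                    double gamma_x, double gamma_z,
                    double hill_height, arma::vec hill_width, int deposit_stride,
                    int n_steps, double dt, int save_stride,
                    arma::vec zlo, arma::vec zhi, double kwall, double wt_dT,
                    arma::vec lower, arma::vec upper) {
  Surface s = parse_surface(spec);
  int dim = s.dim, ncv = cvdims.n_elem;
  arma::vec x = x0, z = z0, g(dim);
  double nx = std::sqrt(2.0 * KB * T * dt / gamma_x);
  double nz = std::sqrt(2.0 * KB * Tbar * dt / gamma_z);
  int n_save = n_steps / save_stride;
  int n_hills_max = n_steps / deposit_stride;
  arma::mat xs(n_save, dim), zs(n_save, ncv);
  arma::mat hills(n_hills_max, 2 + 2 * ncv); // step, center[ncv], height, width[ncv]
  int nh = 0, isave = 0;
  arma::vec span = upper - lower;
  arma::vec fz(ncv);
  for (int t = 1; t <= n_steps; ++t) {
    surf_energy_grad(s, x, g);
    // coupling forces
    for (int c = 0; c < ncv; ++c) {
      int j = cvdims[c];
      double dv = x[j] - z[c];
      g[j] += kappa_ext * dv;             // force on x is -g
      fz[c] = kappa_ext * dv;             // force on z
      // hill bias force on z: sum_h height * e * (z - ch)/w^2
      for (int hidx = 0; hidx < nh; ++hidx) {
        double e = 0.0;
        for (int c2 = 0; c2 < ncv; ++c2) {
          double d = z[c2] - hills(hidx, 1 + c2);
          double w = hills(hidx, 2 + ncv + c2);
          e += d * d / (2.0 * w * w);
        }
        if (e < 30.0) {
          double amp = hills(hidx, 1 + ncv) * std::exp(-e);
          double d = z[c] - hills(hidx, 1 + c);
          double w = hills(hidx, 2 + ncv + c);
          fz[c] += amp * d / (w * w);
        }
      }
      // soft walls on z
      if (z[c] < zlo[c]) fz[c] += kwall * (zlo[c] - z[c]);
      if (z[c] > zhi[c]) fz[c] -= kwall * (z[c] - zhi[c]);
    }
    for (int j = 0; j < dim; ++j) {
      x[j] += -dt / gamma_x * g[j] + nx * norm_rand();
      if (x[j] < lower[j] - 10.0 * span[j] || x[j] > upper[j] + 10.0 * span[j] ||
          !std::isfinite(x[j]))
        stop("tamd_metad instability at step %d (dt = %g too large?)", t, dt);
    }
    for (int c = 0; c < ncv; ++c)
      z[c] += dt / gamma_z * fz[c] + nz * norm_rand();
    if (t % deposit_stride == 0 && nh < n_hills_max) {
      double height = hill_height;
      if (wt_dT > 0.0) {
        // well-tempered scaling by current bias at z
        double vb = 0.0;
        for (int hidx = 0; hidx < nh; ++hidx) {
          double e = 0.0;
          for (int c2 = 0; c2 < ncv; ++c2) {
            double d = z[c2] - hills(hidx, 1 + c2);
            double w = hills(hidx, 2 + ncv + c2);
            e += d * d / (2.0 * w * w);
          }
          if (e < 30.0) vb += hills(hidx, 1 + ncv) * std::exp(-e);
        }
        height *= std::exp(-vb / (KB * wt_dT));
      }
      hills(nh, 0) = t;
      for (int c = 0; c < ncv; ++c) hills(nh, 1 + c) = z[c];
      hills(nh, 1 + ncv) = height;
      for (int c = 0; c < ncv; ++c) hills(nh, 2 + ncv + c) = hill_width[c];
      ++nh;
    }
    if (t % save_stride == 0) {
      xs.row(isave) = x.t();
      for (int c = 0; c < ncv; ++c) zs(isave, c) = z[c];
      ++isave;
    }
  }
  return List::create(_["x"] = xs, _["z"] = zs,
                      _["hills"] = hills.rows(0, std::max(nh - 1, 0)),
                      _["n_hills"] = nh);
}

// ---------------------------------------------------------------------------
// Voronoi-cell restricted Langevin sampling for the finite-temperature
// string method: proposals whose nearest image is not the cell's own image
// are rejected (the walker stays put).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List voronoi_sample_cpp(List spec, arma::mat images, int idx, arma::vec x0,
                        int n_steps, double dt, double gamma, double T,
                        int save_stride) {
  Surface s = parse_surface(spec);
  int dim = s.dim, M = images.n_rows;
  arma::vec x = x0, g(dim), prop(dim);
  double noise = std::sqrt(2.0 * KB * T * dt / gamma);
  int n_save = n_steps / save_stride, isave = 0;
  arma::mat out(n_save, dim);
  long accepted = 0;
  for (int t = 1; t <= n_steps; ++t) {
    surf_energy_grad(s, x, g);
    for (int j = 0; j < dim; ++j)
      prop[j] = x[j] - dt / gamma * g[j] + noise * norm_rand();
    // nearest image (ties to the lowest index)
    int best = 0; double bestd = 1e300;
    for (int m = 0; m < M; ++m) {
      double d2 = 0.0;
      for (int j = 0; j < dim; ++j) {
        double d = prop[j] - images(m, j);
        d2 += d * d;
      }
      if (d2 < bestd) { bestd = d2; best = m; }
    }
    if (best == idx) { x = prop; ++accepted; }
    if (t % save_stride == 0) out.row(isave++) = x.t();
  }
  return List::create(_["samples"] = out,
                      _["acceptance"] = (double)accepted / n_steps,
                      _["final"] = x);
}
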