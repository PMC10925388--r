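// Minimal HDF5 binding for the conformer-dataset layout: one level of
// groups at the root, each holding double or integer datasets. Data cross
// the R/C++ boundary as flat C-order buffers plus a dims vector; layout
// conversion happens on the R side.

#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>

using namespace Rcpp;

static void stopH5(const std::string& msg) { Rcpp::stop("HDF5 error: " + msg); }

// [[Rcpp::export]]
void cppH5Write(std::string path, List groups) {
  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (file < 0) stopH5("cannot create file " + path);
  if (groups.size() == 0) { H5Fclose(file); return; }
  CharacterVector gnames = groups.names();
  for (R_xlen_t g = 0; g < groups.size(); ++g) {
    std::string gname = as<std::string>(gnames[g]);
    hid_t grp = H5Gcreate2(file, gname.c_str(), H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (grp < 0) { H5Fclose(file); stopH5("cannot create group " + gname); }
    List entry = groups[g];
    CharacterVector dnames = entry.names();
    for (R_xlen_t d = 0; d < entry.size(); ++d) {
      std::string dname = as<std::string>(dnames[d]);
      List ds = entry[d];
      IntegerVector dimsR = as<IntegerVector>(ds["dims"]);
      std::vector<hsize_t> dims(dimsR.size());
      for (int k = 0; k < dimsR.size(); ++k) dims[k] = (hsize_t)dimsR[k];
      hid_t space = H5Screate_simple((int)dims.size(), dims.data(), NULL);
      SEXP data = ds["data"];
      herr_t st;
      if (TYPEOF(data) == INTSXP) {
        hid_t dset = H5Dcreate2(grp, dname.c_str(), H5T_STD_I32LE, space,
                                H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
        st = H5Dwrite(dset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                      INTEGER(data));
        H5Dclose(dset);
      } else {
        hid_t dset = H5Dcreate2(grp, dname.c_str(), H5T_IEEE_F64LE, space,
                                H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
        st = H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                      REAL(data));
        H5Dclose(dset);
      }
      H5Sclose(space);
      if (st < 0) { H5Gclose(grp); H5Fclose(file); stopH5("write failed for " + gname + "/" + dname); }
    }
    H5Gclose(grp);
  }
  H5Fclose(file);
}

static List readDataset(hid_t grp, const std::string& name) {
  hid_t dset = H5Dopen2(grp, name.c_str(), H5P_DEFAULT);
  if (dset < 0) stopH5("cannot open dataset " + name);
  hid_t space = H5Dget_space(dset);
  int rank = H5Sget_simple_extent_ndims(space);
  std::vector<hsize_t> dims(rank > 0 ? rank : 1, 1);
  if (rank > 0) H5Sget_simple_extent_dims(space, dims.data(), NULL);
  hsize_t total = 1;
  for (int k = 0; k < rank; ++k) total *= dims[k];
  hid_t dtype = H5Dget_type(dset);
  H5T_class_t cls = H5Tget_class(dtype);
  IntegerVector dimsR(rank > 0 ? rank : 1, 1);
  for (int k = 0; k < rank; ++k) dimsR[k] = (int)dims[k];
  List out;
  if (cls == H5T_INTEGER) {
    IntegerVector v((R_xlen_t)total);
    if (H5Dread(dset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT, INTEGER(v)) < 0)
      stopH5("read failed for " + name);
    out = List::create(_["data"] = v, _["dims"] = dimsR);
  } else {
    NumericVector v((R_xlen_t)total);
    if (H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(v)) < 0)
      stopH5("read failed for " + name);
    out = List::create(_["data"] = v, _["dims"] = dimsR);
  }
  H5Tclose(dtype);
  H5Sclose(space);
  H5Dclose(dset);
  return out;
}

static std::vector<std::string> childNames(hid_t loc) {
  H5G_info_t info;
  H5Gget_info(loc, &info);
  std::vector<std::string> names;
  for (hsize_t k = 0; k < info.nlinks; ++k) {
    ssize_t len = H5Lget_name_by_idx(loc, ".", H5_INDEX_NAME, H5_ITER_INC, k,
                                     NULL, 0, H5P_DEFAULT);
    std::string nm(len, '\0');
    H5Lget_name_by_idx(loc, ".", H5_INDEX_NAME, H5_ITER_INC, k,
                       &nm[0], len + 1, H5P_DEFAULT);
    names.push_back(nm);
  }
  return names;
}

// [[Rcpp::export]]
List cppH5Read(std::string path) {
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stopH5("cannot open file " + path);
  std::vector<std::string> gnames = childNames(file);
  List out(gnames.size());
  CharacterVector outNames(gnames.size());
  for (size_t g = 0; g < gnames.size(); ++g) {
    outNames[g] = gnames[g];
    H5O_info_t oinfo;
#if H5_VERSION_GE(1, 12, 0)
    H5Oget_info_by_name3(file, gnames[g].c_str(), &oinfo, H5O_INFO_BASIC, H5P_DEFAULT);
#else
    H5Oget_info_by_name(file, gnames[g].c_str(), &oinfo, H5P_DEFAULT);
#endif
    if (oinfo.type != H5O_TYPE_GROUP) {
      H5Fclose(file);
      stopH5("root entry '" + gnames[g] + "' is not a group (unexpected layout)");
    }
    hid_t grp = H5Gopen2(file, gnames[g].c_str(), H5P_DEFAULT);
    std::vector<std::string> dnames = childNames(grp);
    List entry(dnames.size());
    CharacterVector entryNames(dnames.size());
    for (size_t d = 0; d < dnames.size(); ++d) {
      entryNames[d] = dnames[d];
      entry[d] = readDataset(grp, dnames[d]);
    }
    entry.names() = entryNames;
    H5Gclose(grp);
    out[g] = entry;
  }
  out.names() = outNames;
  H5Fclose(file);
  return out;
}
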