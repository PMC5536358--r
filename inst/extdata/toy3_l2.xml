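<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="toy3_l2">
    <listOfCompartments>
      <compartment id="c" name="cytosol"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_c" name="glucose" compartment="c" boundaryCondition="false"/>
      <species id="atp_c" name="ATP" compartment="c" boundaryCondition="false"/>
      <species id="glc_b" name="glucose boundary" compartment="c" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE_ASSOCIATION: </p>
        </body></notes>
        <listOfReactants>
          <speciesReference species="glc_b" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1000"/>
            <parameter id="UPPER_BOUND" value="10"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="CONV" reversible="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE_ASSOCIATION: (Hk1 and Gpi1) or Hk2</p>
        </body></notes>
        <listOfReactants>
          <speciesReference species="glc_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="atp_c" stoichiometry="2"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="DM_atp" reversible="false">
        <listOfReactants>
          <speciesReference species="atp_c" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
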