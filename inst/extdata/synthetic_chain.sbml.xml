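<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic two-enzyme reversible Michaelis-Menten chain, written by
     hand as an importer test fixture. Not a deposited model. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="synthetic_chain" name="synthetic linear chain">
    <listOfCompartments>
      <compartment id="cell" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="X0" compartment="cell" initialConcentration="100" boundaryCondition="true"/>
      <species id="S1" compartment="cell" initialConcentration="10"/>
      <species id="Xn" compartment="cell" initialConcentration="1" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="scale" value="1"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="E1" reversible="true">
        <listOfReactants>
          <speciesReference species="X0" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="S1" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><divide/>
              <apply><times/>
                <ci>scale</ci>
                <ci>V</ci>
                <apply><minus/>
                  <apply><divide/><ci>X0</ci><ci>Ks</ci></apply>
                  <apply><divide/><ci>S1</ci>
                    <apply><times/><ci>Ks</ci><ci>Keq</ci></apply>
                  </apply>
                </apply>
              </apply>
              <apply><plus/>
                <cn>1</cn>
                <apply><divide/><ci>X0</ci><ci>Ks</ci></apply>
                <apply><divide/><ci>S1</ci><ci>Kp</ci></apply>
              </apply>
            </apply>
          </math>
          <listOfParameters>
            <parameter id="V" value="100"/>
            <parameter id="Ks" value="10"/>
            <parameter id="Kp" value="20"/>
            <parameter id="Keq" value="10"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="E2" reversible="true">
        <listOfReactants>
          <speciesReference species="S1" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Xn" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><divide/>
              <apply><times/>
                <ci>V</ci>
                <apply><minus/>
                  <apply><divide/><ci>S1</ci><ci>Ks</ci></apply>
                  <apply><divide/><ci>Xn</ci>
                    <apply><times/><ci>Ks</ci><ci>Keq</ci></apply>
                  </apply>
                </apply>
              </apply>
              <apply><plus/>
                <cn>1</cn>
                <apply><divide/><ci>S1</ci><ci>Ks</ci></apply>
                <apply><divide/><ci>Xn</ci><ci>Kp</ci></apply>
              </apply>
            </apply>
          </math>
          <listOfParameters>
            <parameter id="V" value="200"/>
            <parameter id="Ks" value="15"/>
            <parameter id="Kp" value="30"/>
            <parameter id="Keq" value="5"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
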